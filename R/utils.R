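# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All seeded package operations funnel through this so
# that library use never clobbers the user's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

# Derive a per-item seed from a dataset seed by a fixed counter scheme; stays
# inside the 32-bit integer range.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) + 7919 * as.double(counter)) %% 2147483647L)
}

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(field, "must be a single finite number")
  }
  if (integer && x != round(x)) stop_invalid(field, "must be an integer")
  if (x < min) stop_invalid(field, sprintf("must be >= %s", min))
  if (x > max) stop_invalid(field, sprintf("must be <= %s", max))
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_rgb <- function(pixels) is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L

# Luminance conversion used whenever a grayscale view of an RGB image is needed.
to_gray <- function(pixels) {
  if (is_rgb(pixels)) {
    0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  } else {
    pixels
  }
}

# Shift a matrix by (dr, dc), padding vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- max(1, 1 - dr):min(h, h - dr)
  src_c <- max(1, 1 - dc):min(w, w - dc)
  if (length(src_r) < 1 || length(src_c) < 1) return(out)
  out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  out
}

# Band-limited noise: white noise smoothed with a separable box filter whose
# width tracks the requested correlation scale, then standardised.
textured_noise <- function(h, w, scale) {
  z <- matrix(rnorm(h * w), h, w)
  width <- max(1L, as.integer(round(scale)))
  if (width > 1L) {
    k <- rep(1 / width, width)
    z <- t(apply(z, 1, function(r) stats::filter(r, k, circular = TRUE)))
    z <- apply(z, 2, function(cl) stats::filter(cl, k, circular = TRUE))
  }
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  matrix(as.numeric(z), h, w)
}
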