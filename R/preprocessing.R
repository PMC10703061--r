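#' Median filtering with edge-replication padding
#'
#' Each output pixel is the median of its `window` x `window` neighbourhood;
#' borders are handled by replicating the edge rows/columns. RGB arrays are
#' filtered per channel.
#'
#' @param image Numeric matrix (grayscale) or H x W x 3 array.
#' @param window Odd window side length, >= 3.
#' @return Filtered image of the same shape.
#' @export
median_filter <- function(image, window = 3L) {
  check_number(window, "window", min = 3, integer = TRUE)
  if (window %% 2 == 0) stop_invalid("window", "must be odd")
  if (is_rgb(image)) {
    out <- image
    for (ch in 1:3) out[, , ch] <- median_filter(image[, , ch], window)
    return(out)
  }
  h <- nrow(image); w <- ncol(image)
  r <- (window - 1L) %/% 2L
  # edge replication via clamped index lookup
  ridx <- clip(seq_len(h + 2 * r) - r, 1, h)
  cidx <- clip(seq_len(w + 2 * r) - r, 1, w)
  pad <- image[ridx, cidx, drop = FALSE]
  stack <- matrix(0, h * w, window * window)
  s <- 0L
  for (dr in 0:(window - 1L)) {
    for (dc in 0:(window - 1L)) {
      s <- s + 1L
      stack[, s] <- as.vector(pad[dr + seq_len(h), dc + seq_len(w)])
    }
  }
  matrix(apply(stack, 1, median), h, w)
}

#' Binary mask dilation (Minkowski sum)
#'
#' @param mask Binary matrix (0/1 or logical).
#' @param element Odd-sided binary structuring element; default 3 x 3 of ones.
#'   The origin is the centre cell.
#' @return Dilated binary (integer 0/1) matrix, a superset of the input.
#' @export
dilate_mask <- function(mask, element = matrix(1L, 3, 3)) {
  stopifnot(is.matrix(mask), is.matrix(element))
  if (nrow(element) %% 2 == 0 || ncol(element) %% 2 == 0) {
    stop_invalid("element", "side lengths must be odd")
  }
  m <- (mask != 0) * 1L
  cy <- (nrow(element) + 1L) %/% 2L
  cx <- (ncol(element) + 1L) %/% 2L
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(element))) {
    for (j in seq_len(ncol(element))) {
      if (element[i, j] != 0) {
        out <- out | shift_matrix(m, i - cy, j - cx, fill = 0L)
      }
    }
  }
  out * 1L
}

#' Configuration for diffusion inpainting
#'
#' @param max_iterations Maximum Jacobi sweeps (>= 1).
#' @param tolerance Convergence threshold: maximum absolute per-pixel change
#'   per sweep, on the internal \[0, 1\] intensity scale.
#' @param dilation_element Structuring element used to dilate the mask before
#'   filling, so that spot rims are reconstructed too.
#' @return An `inpaint_config` list.
#' @export
inpaint_config <- function(max_iterations = 500L, tolerance = 1e-3,
                           dilation_element = matrix(1L, 3, 3)) {
  check_number(max_iterations, "max_iterations", min = 1, integer = TRUE)
  check_number(tolerance, "tolerance", min = 1e-15)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 dilation_element = dilation_element),
            class = "inpaint_config")
}

#' Harmonic diffusion inpainting of masked regions
#'
#' Treats intensities as a fluid that flows into the masked holes: the mask is
#' first dilated by `config$dilation_element`, then masked pixels are replaced
#' by iterative 4-neighbour (Jacobi) averaging until the largest per-pixel
#' change falls below `config$tolerance` or `config$max_iterations` sweeps.
#' Unmasked pixels are never modified. The converged solution is discretely
#' harmonic, hence obeys the maximum principle: filled values stay within the
#' range of the surrounding boundary values.
#'
#' @param image Numeric matrix or H x W x 3 array in \[0, 255\].
#' @param mask Binary matrix marking pixels to reconstruct.
#' @param config An [inpaint_config()].
#' @return Inpainted image, same shape and scale as the input.
#' @export
inpaint_diffusion <- function(image, mask, config = inpaint_config()) {
  stopifnot(is.matrix(mask))
  if (is_rgb(image)) {
    out <- image
    for (ch in 1:3) out[, , ch] <- inpaint_diffusion(image[, , ch], mask, config)
    return(out)
  }
  if (all(mask != 0)) stop("mask covers the entire image: no boundary data")
  m <- dilate_mask(mask, config$dilation_element)
  if (all(m != 0)) stop("dilated mask covers the entire image: no boundary data")
  if (!any(m != 0)) return(image)
  if (any(m[1, ] != 0) || any(m[nrow(m), ] != 0) ||
      any(m[, 1] != 0) || any(m[, ncol(m)] != 0)) {
    stop("mask (after dilation) must lie strictly inside the image")
  }
  u <- image / 255
  hole <- m != 0
  u[hole] <- mean(u[!hole])   # neutral initialisation, converges regardless
  for (it in seq_len(config$max_iterations)) {
    avg <- (shift_matrix(u, 1, 0) + shift_matrix(u, -1, 0) +
            shift_matrix(u, 0, 1) + shift_matrix(u, 0, -1)) / 4
    delta <- max(abs(avg[hole] - u[hole]))
    u[hole] <- avg[hole]
    if (delta < config$tolerance) break
  }
  out <- image
  out[hole] <- clip(u[hole], 0, 1) * 255
  out
}

#' Augmentation operators for labelled images
#'
#' Applies an ordered list of augmentation operations, one output image per
#' operation application (`sliding_crop` yields one output per window). Labels
#' and, where geometry permits, tumour masks are propagated.
#'
#' Supported ops (each a list with a `type` field):
#' \describe{
#'   \item{`horizontal_flip`, `vertical_flip`}{mirror the image (involutions).}
#'   \item{`rescale`}{`size = c(h, w)` bilinear resize.}
#'   \item{`random_crop`}{`size = c(h, w)`, `seed`; a seeded subwindow.}
#'   \item{`sliding_crop`}{`size = c(h, w)`, `stride`; all windows on the grid.}
#'   \item{`texture_kernel_paste`}{`kernel = side`, `n_pastes`, `seed`; copies
#'     square patches from the image onto itself at seeded locations (hard
#'     paste), enriching texture variety without leaving the class.}
#' }
#'
#' @param image A `labeled_image`.
#' @param ops List of operation descriptors (see Details).
#' @return List of augmented `labeled_image` objects.
#' @export
augment_image <- function(image, ops) {
  stopifnot(inherits(image, "labeled_image"), is.list(ops))
  out <- list()
  for (op in ops) {
    res <- apply_augment_op(image, op)
    out <- c(out, res)
  }
  out
}

apply_augment_op <- function(image, op) {
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  flip <- function(p, dim_i) {
    idx <- rev(seq_len(dim(p)[dim_i]))
    if (is_rgb(p)) {
      if (dim_i == 1) p[idx, , , drop = FALSE] else p[, idx, , drop = FALSE]
    } else {
      if (dim_i == 1) p[idx, , drop = FALSE] else p[, idx, drop = FALSE]
    }
  }
  crop <- function(p, r0, c0, ch, cw) {
    if (is_rgb(p)) p[r0:(r0 + ch - 1), c0:(c0 + cw - 1), , drop = FALSE]
    else p[r0:(r0 + ch - 1), c0:(c0 + cw - 1), drop = FALSE]
  }
  mk <- function(p, mask = image$tumor_mask) new_labeled_image(p, image$label, mask)
  switch(op$type,
    horizontal_flip = list(mk(flip(px, 2),
                              if (!is.null(image$tumor_mask)) flip(image$tumor_mask, 2))),
    vertical_flip = list(mk(flip(px, 1),
                            if (!is.null(image$tumor_mask)) flip(image$tumor_mask, 1))),
    rescale = list(mk(rescale_image(px, op$size),
                      if (!is.null(image$tumor_mask)) {
                        (rescale_image(image$tumor_mask * 1.0, op$size) > 0.5) * 1L
                      })),
    random_crop = {
      ch <- op$size[1]; cw <- op$size[2]
      if (ch > h || cw > w) stop_invalid("size", "crop larger than image")
      rc <- with_seed(op$seed %||% 1L,
                      c(sample.int(h - ch + 1L, 1L), sample.int(w - cw + 1L, 1L)))
      list(mk(crop(px, rc[1], rc[2], ch, cw),
              if (!is.null(image$tumor_mask)) crop(image$tumor_mask, rc[1], rc[2], ch, cw)))
    },
    sliding_crop = {
      ch <- op$size[1]; cw <- op$size[2]; stride <- op$stride %||% ch
      if (ch > h || cw > w) stop_invalid("size", "crop larger than image")
      res <- list()
      for (r0 in seq(1L, h - ch + 1L, by = stride)) {
        for (c0 in seq(1L, w - cw + 1L, by = stride)) {
          res[[length(res) + 1L]] <-
            mk(crop(px, r0, c0, ch, cw),
               if (!is.null(image$tumor_mask)) crop(image$tumor_mask, r0, c0, ch, cw))
        }
      }
      res
    },
    texture_kernel_paste = {
      k <- op$kernel
      if (k > h || k > w) stop_invalid("kernel", "patch larger than image")
      n_pastes <- op$n_pastes %||% 1L
      p2 <- px
      with_seed(op$seed %||% 1L, {
        for (i in seq_len(n_pastes)) {
          sr <- sample.int(h - k + 1L, 1L); sc <- sample.int(w - k + 1L, 1L)
          dr <- sample.int(h - k + 1L, 1L); dc <- sample.int(w - k + 1L, 1L)
          if (is_rgb(p2)) {
            p2[dr:(dr + k - 1), dc:(dc + k - 1), ] <- px[sr:(sr + k - 1), sc:(sc + k - 1), ]
          } else {
            p2[dr:(dr + k - 1), dc:(dc + k - 1)] <- px[sr:(sr + k - 1), sc:(sc + k - 1)]
          }
        }
      })
      list(mk(p2))
    },
    stop_invalid("type", sprintf("unknown augmentation op `%s`", op$type))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bilinear resize to size = c(h, w); used by the rescale augmentation.
rescale_image <- function(pixels, size) {
  th <- size[1]; tw <- size[2]
  interp_plane <- function(m) {
    h <- nrow(m); w <- ncol(m)
    ry <- if (th == 1) rep(1, 1) else seq(1, h, length.out = th)
    rx <- if (tw == 1) rep(1, 1) else seq(1, w, length.out = tw)
    y0 <- floor(ry); y1 <- pmin(y0 + 1, h); fy <- ry - y0
    x0 <- floor(rx); x1 <- pmin(x0 + 1, w); fx <- rx - x0
    a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
      m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
      m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
      m[y1, x1, drop = FALSE] * outer(fy, fx)
    a
  }
  if (is_rgb(pixels)) {
    out <- array(0, dim = c(th, tw, 3))
    for (ch in 1:3) out[, , ch] <- interp_plane(pixels[, , ch])
    out
  } else {
    interp_plane(pixels)
  }
}
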