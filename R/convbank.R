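#' Convolutional filter-bank configuration
#'
#' Describes an untrained, seeded bank of random convolution filters followed
#' by ReLU activation and non-overlapping max-pooling. The kernels are fixed
#' at construction (standard normal weights scaled by `1/kernel`), so the
#' extractor is deterministic given the seed and never trained.
#'
#' @param n_filters Number of filters (>= 1).
#' @param kernel Odd kernel side length.
#' @param stride Convolution stride (>= 1).
#' @param bias Per-filter additive bias (scalar recycled or length
#'   `n_filters`).
#' @param pool Max-pooling window side (>= 1, non-overlapping).
#' @param seed Integer seed for the kernel draw.
#' @param kernels Optional explicit list of `kernel x kernel` matrices
#'   overriding the seeded draw (e.g. a nonnegative bank).
#' @return A `conv_config` list with the materialised `kernels`.
#' @export
conv_config <- function(n_filters = 8L, kernel = 3L, stride = 1L, bias = 0,
                        pool = 2L, seed = 1L, kernels = NULL) {
  check_number(n_filters, "n_filters", min = 1, integer = TRUE)
  check_number(kernel, "kernel", min = 1, integer = TRUE)
  if (kernel %% 2 == 0) stop_invalid("kernel", "must be odd")
  check_number(stride, "stride", min = 1, integer = TRUE)
  check_number(pool, "pool", min = 1, integer = TRUE)
  if (is.null(kernels)) {
    kernels <- with_seed(seed, lapply(seq_len(n_filters), function(i) {
      matrix(rnorm(kernel * kernel, sd = 1 / kernel), kernel, kernel)
    }))
  } else {
    stopifnot(length(kernels) == n_filters)
  }
  bias <- rep_len(bias, n_filters)
  structure(list(n_filters = as.integer(n_filters), kernel = as.integer(kernel),
                 stride = as.integer(stride), bias = bias,
                 pool = as.integer(pool), seed = as.integer(seed),
                 kernels = kernels),
            class = "conv_config")
}

# Valid-mode 2-D cross-correlation implemented by shift-and-add.
conv2_valid <- function(image, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  oh <- nrow(image) - kh + 1L; ow <- ncol(image) - kw + 1L
  out <- matrix(0, oh, ow)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (kern[i, j] != 0) {
        out <- out + kern[i, j] * image[i:(i + oh - 1L), j:(j + ow - 1L)]
      }
    }
  }
  out
}

# Non-overlapping max-pooling with window p; trailing remainder is dropped.
max_pool <- function(m, p) {
  oh <- nrow(m) %/% p; ow <- ncol(m) %/% p
  if (oh < 1 || ow < 1) stop("pool window larger than feature map")
  out <- matrix(-Inf, oh, ow)
  for (dr in seq_len(p)) {
    for (dc in seq_len(p)) {
      out <- pmax(out, m[seq(dr, by = p, length.out = oh),
                         seq(dc, by = p, length.out = ow), drop = FALSE])
    }
  }
  out
}

#' Untrained convolutional filter-bank features
#'
#' For each seeded random kernel: valid-mode convolution (with stride), plus
#' bias, ReLU `max(0, x)`, then non-overlapping max-pooling; all pooled maps
#' are flattened into one named vector. Pixel intensities are taken on the
#' \[0, 1\] scale internally.
#'
#' @param image Grayscale matrix or RGB array (luminance used), values 0-255.
#' @param config A [conv_config()].
#' @return Named numeric feature vector
#'   (`conv_f<filter>_r<row>_c<col>` entries), all `>= 0`.
#' @export
conv_filterbank_features <- function(image, config = conv_config()) {
  g <- to_gray(image) / 255
  if (nrow(g) <= config$kernel || ncol(g) <= config$kernel) {
    stop("image must be larger than the kernel")
  }
  vals <- numeric(0)
  nms <- character(0)
  for (f in seq_len(config$n_filters)) {
    fm <- conv2_valid(g, config$kernels[[f]])
    if (config$stride > 1L) {
      fm <- fm[seq(1, nrow(fm), by = config$stride),
               seq(1, ncol(fm), by = config$stride), drop = FALSE]
    }
    fm <- pmax(fm + config$bias[f], 0)
    pooled <- max_pool(fm, config$pool)
    vals <- c(vals, as.vector(pooled))
    idx <- expand.grid(r = seq_len(nrow(pooled)), c = seq_len(ncol(pooled)))
    nms <- c(nms, sprintf("conv_f%d_r%d_c%d", f, idx$r, idx$c))
  }
  names(vals) <- nms
  vals
}

#' Fuse two named feature vectors
#'
#' Concatenation with `a`'s entries first; the name spaces must be disjoint.
#'
#' @param a,b Named numeric vectors.
#' @return The fused named vector of length `length(a) + length(b)`.
#' @export
fuse_features <- function(a, b) {
  if (length(a) == 0) return(b)
  if (length(b) == 0) return(a)
  if (any(names(a) %in% names(b))) {
    stop("feature name collision between the two vectors")
  }
  c(a, b)
}
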