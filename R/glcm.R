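#' GLCM configuration
#'
#' @param levels Number of gray levels L after quantisation (>= 2).
#' @param offsets List of `(d_row, d_col)` integer pairs; defaults to the four
#'   standard directions (0,1), (1,0), (1,1), (1,-1). Offsets are applied on a
#'   0-based row-major grid as `(row + d_row, col + d_col)`.
#' @param symmetric If `TRUE`, counts are symmetrised (`C + t(C)`).
#' @param normalize If `TRUE`, counts are divided by their total so the matrix
#'   is a joint probability.
#' @return A `glcm_config` list.
#' @export
glcm_config <- function(levels = 8L,
                        offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)),
                        symmetric = TRUE, normalize = TRUE) {
  check_number(levels, "levels", min = 2, integer = TRUE)
  for (off in offsets) {
    if (length(off) != 2L || all(off == 0)) {
      stop_invalid("offsets", "each offset must be a nonzero (d_row, d_col) pair")
    }
  }
  structure(list(levels = as.integer(levels), offsets = offsets,
                 symmetric = isTRUE(symmetric), normalize = isTRUE(normalize)),
            class = "glcm_config")
}

#' Uniform gray-level quantisation
#'
#' Bins intensities in \[0, 255\] into `L` equal-width bins `0..L-1`; the
#' value 255 maps to `L - 1`.
#'
#' @param image Numeric matrix (or RGB array, converted to luminance first).
#' @param L Number of levels (>= 2).
#' @return Integer matrix over `{0, ..., L-1}`.
#' @export
quantize_gray <- function(image, L = 8L) {
  check_number(L, "L", min = 2, integer = TRUE)
  g <- to_gray(image)
  q <- floor(g * L / 256)
  q[q > L - 1] <- L - 1L
  q[q < 0] <- 0L
  matrix(as.integer(q), nrow(g), ncol(g))
}

#' Gray-level co-occurrence matrix at one offset
#'
#' `C(i, j)` counts the ordered pixel pairs `(p, p + offset)` that are both in
#' bounds and have quantised values `(i, j)`. With `symmetric`, `C` becomes
#' `C + t(C)`; with `normalize`, entries are divided by their total.
#'
#' @param image Integer matrix with values in `{0, ..., L-1}`.
#' @param offset Integer pair `(d_row, d_col)`.
#' @param config A [glcm_config()]; its `levels`, `symmetric` and `normalize`
#'   fields are honoured (the `offsets` list is ignored here).
#' @return A `glcm_matrix`: list with `matrix` (L x L), `offset`, `normalized`.
#' @export
compute_glcm <- function(image, offset, config = glcm_config()) {
  stopifnot(is.matrix(image))
  L <- config$levels
  if (any(image < 0) || any(image >= L)) {
    stop_invalid("image", sprintf("values must lie in 0..%d; quantize first", L - 1L))
  }
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  h <- nrow(image); w <- ncol(image)
  rows <- seq_len(h); cols <- seq_len(w)
  src_r <- rows[rows + dr >= 1 & rows + dr <= h]
  src_c <- cols[cols + dc >= 1 & cols + dc <= w]
  C <- matrix(0, L, L)
  if (length(src_r) > 0 && length(src_c) > 0) {
    a <- image[src_r, src_c, drop = FALSE]
    b <- image[src_r + dr, src_c + dc, drop = FALSE]
    counts <- tabulate(as.vector(a) * L + as.vector(b) + 1L, nbins = L * L)
    C <- matrix(counts, L, L, byrow = TRUE)   # row index i = first value
  }
  if (config$symmetric) C <- C + t(C)
  normalized <- FALSE
  total <- sum(C)
  if (config$normalize && total > 0) {
    C <- C / total
    normalized <- TRUE
  }
  structure(list(matrix = C, offset = c(dr, dc), normalized = normalized),
            class = "glcm_matrix")
}

#' Haralick statistics of a normalised GLCM
#'
#' Computes the four standard texture statistics of a joint gray-level
#' probability `p(i, j)`:
#' contrast `sum (i-j)^2 p`, energy `sum p^2`, homogeneity
#' `sum p / (1 + |i-j|)`, and correlation
#' `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)` with marginal means and
#' standard deviations. If either marginal SD is zero the correlation is
#' reported as 0 and flagged degenerate.
#'
#' @param glcm A normalised `glcm_matrix` (or a plain matrix summing to 1).
#' @return Named numeric vector `(contrast, correlation, energy, homogeneity)`
#'   with attribute `degenerate` (logical) for the correlation.
#' @export
glcm_statistics <- function(glcm) {
  p <- if (inherits(glcm, "glcm_matrix")) {
    if (!glcm$normalized) stop("glcm must be normalized")
    glcm$matrix
  } else {
    if (abs(sum(glcm) - 1) > 1e-9) stop("glcm must be normalized")
    glcm
  }
  L <- nrow(p)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  contrast <- sum((i - j)^2 * p)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(i - j)))
  pi_m <- rowSums(p); pj_m <- colSums(p)
  lv <- 0:(L - 1)
  mu_i <- sum(lv * pi_m); mu_j <- sum(lv * pj_m)
  sd_i <- sqrt(sum((lv - mu_i)^2 * pi_m))
  sd_j <- sqrt(sum((lv - mu_j)^2 * pj_m))
  degenerate <- sd_i * sd_j == 0
  correlation <- if (degenerate) 0 else sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  out <- c(contrast = contrast, correlation = correlation,
           energy = energy, homogeneity = homogeneity)
  attr(out, "degenerate") <- degenerate
  out
}

#' Handcrafted GLCM texture feature vector
#'
#' Quantises the image, computes one normalised GLCM per configured offset and
#' extracts the four Haralick statistics from each, giving a vector of length
#' `4 * length(offsets)` with stable names
#' `glcm_d<row>_<col>_<statistic>`.
#'
#' @param image Grayscale matrix or RGB array (luminance is used).
#' @param config A [glcm_config()].
#' @return Named numeric feature vector.
#' @export
handcrafted_features <- function(image, config = glcm_config()) {
  q <- quantize_gray(image, config$levels)
  cfg <- config
  cfg$normalize <- TRUE
  vals <- numeric(0)
  for (off in config$offsets) {
    g <- compute_glcm(q, off, cfg)
    s <- glcm_statistics(g)
    names(s) <- sprintf("glcm_d%d_%d_%s", off[1], off[2], names(s))
    vals <- c(vals, s)
  }
  vals
}
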