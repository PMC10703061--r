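#' Segmentation configuration
#'
#' @param n_hue_levels Number of hue levels for multi-level thresholding (>= 2).
#' @param K Number of K-means colour clusters (>= 1), default 3.
#' @param white_fill RGB triple used to overwrite the discarded cluster.
#' @param seed Integer seed for the K-means initialisation.
#' @param max_kmeans_iter Maximum Lloyd iterations.
#' @param kmeans_tol Centroid-shift convergence tolerance (RGB units).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(n_hue_levels = 3L, K = 3L,
                                white_fill = c(255, 255, 255), seed = 1L,
                                max_kmeans_iter = 100L, kmeans_tol = 1e-4) {
  check_number(n_hue_levels, "n_hue_levels", min = 2, integer = TRUE)
  check_number(K, "K", min = 1, integer = TRUE)
  stopifnot(length(white_fill) == 3L)
  structure(list(n_hue_levels = as.integer(n_hue_levels), K = as.integer(K),
                 white_fill = as.numeric(white_fill), seed = as.integer(seed),
                 max_kmeans_iter = as.integer(max_kmeans_iter),
                 kmeans_tol = kmeans_tol),
            class = "segmentation_config")
}

# Between-class-variance (multi-level Otsu) threshold search on a histogram.
# Returns the bin-boundary thresholds (on [0,1]) maximising sigma^2_B by
# exhaustive enumeration; tractable for n_levels <= 4.
otsu_multilevel_thresholds <- function(counts, n_levels, n_bins = length(counts)) {
  p <- counts / sum(counts)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  mu_total <- sum(p * mids)
  cuts <- combn(n_bins - 1L, n_levels - 1L)
  best <- -Inf; best_cut <- cuts[, 1]
  for (ci in seq_len(ncol(cuts))) {
    edges <- c(0L, cuts[, ci], n_bins)
    sigma_b <- 0
    ok <- TRUE
    for (k in seq_len(n_levels)) {
      idx <- (edges[k] + 1L):edges[k + 1L]
      wk <- sum(p[idx])
      if (wk > 0) {
        muk <- sum(p[idx] * mids[idx]) / wk
        sigma_b <- sigma_b + wk * (muk - mu_total)^2
      }
    }
    if (ok && sigma_b > best) { best <- sigma_b; best_cut <- cuts[, ci] }
  }
  best_cut / n_bins
}

#' Multi-level Otsu thresholding of the hue channel
#'
#' Converts an RGB image to HSV, stretches the hue channel linearly to the
#' full \[0, 1\] range, and picks `n_levels - 1` thresholds on a 64-bin hue
#' histogram by exhaustive maximisation of the between-class variance
#' (multi-level Otsu). Each pixel is labelled with its hue level.
#'
#' @param image H x W x 3 RGB array in \[0, 255\].
#' @param n_levels Number of levels (>= 2, <= 4 for tractable search).
#' @return A list: `labels` (H x W integer matrix, levels `0..n_levels-1`),
#'   `thresholds` (increasing values in \[0, 1\]), `hue` (normalised hue).
#' @export
hue_multilevel_threshold <- function(image, n_levels = 3L) {
  if (!is_rgb(image)) {
    stop("hue thresholding needs an RGB image; convert grayscale input to RGB first")
  }
  check_number(n_levels, "n_levels", min = 2, max = 4, integer = TRUE)
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]), as.vector(image[, , 3]))
  hue <- grDevices::rgb2hsv(rgb, maxColorValue = 255)[1, ]
  rng <- range(hue)
  hue_n <- if (rng[2] > rng[1]) (hue - rng[1]) / (rng[2] - rng[1]) else hue * 0
  counts <- tabulate(pmin(floor(hue_n * 64) + 1L, 64L), nbins = 64L)
  if (sum(counts > 0) <= 1L) {
    # constant hue: degenerate thresholds at the histogram edge, single label
    thr <- seq_len(n_levels - 1L) / 64 * 0  # all at 0 boundary is meaningless;
    thr <- (64 - rev(seq_len(n_levels - 1L))) / 64   # park at the upper edge
    labels <- matrix(0L, h, w)
    return(list(labels = labels, thresholds = thr, hue = matrix(hue_n, h, w)))
  }
  thr <- otsu_multilevel_thresholds(counts, n_levels)
  labels <- matrix(findInterval(hue_n, thr, left.open = FALSE), h, w)
  list(labels = labels, thresholds = thr, hue = matrix(hue_n, h, w))
}

# Deterministic farthest-point ("k-means++-style") seeding: first centre is a
# seeded uniform pick, each further centre is the point with maximal distance
# to its nearest chosen centre, ties broken by lowest pixel index.
farthest_point_init <- function(x, K, seed) {
  n <- nrow(x)
  centers <- matrix(0, K, ncol(x))
  first <- with_seed(seed, sample.int(n, 1L))
  centers[1, ] <- x[first, ]
  if (K > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (k in 2:K) {
      pick <- which.max(d2)   # which.max takes the first (lowest index) on ties
      centers[k, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[k, ])^2))
    }
  }
  centers
}

#' K-means colour segmentation
#'
#' Lloyd iterations on the RGB triples of all pixels, with deterministic
#' seeded farthest-point initialisation. Converged when the largest centroid
#' shift drops below `config$kmeans_tol` or after `config$max_kmeans_iter`
#' iterations. The within-cluster sum of squares is non-increasing across
#' iterations.
#'
#' @param image H x W x 3 RGB array in \[0, 255\].
#' @param config A [segmentation_config()].
#' @return A list: `labels` (H x W integer matrix of cluster ids `0..K-1`),
#'   `centroids` (K x 3 matrix), `wss_history` (within-cluster sum of squares
#'   after each assignment step).
#' @export
kmeans_color_segment <- function(image, config = segmentation_config()) {
  stopifnot(is_rgb(image))
  h <- dim(image)[1]; w <- dim(image)[2]
  x <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]), as.vector(image[, , 3]))
  K <- config$K
  n_distinct <- nrow(unique(x))
  if (K > n_distinct) {
    stop(sprintf("K = %d exceeds the number of distinct colours (%d)", K, n_distinct))
  }
  centers <- farthest_point_init(x, K, config$seed)
  assign_step <- function(centers) {
    d2 <- matrix(0, nrow(x), K)
    for (k in seq_len(K)) d2[, k] <- rowSums(sweep(x, 2, centers[k, ])^2)
    max.col(-d2, ties.method = "first")
  }
  wss_history <- numeric(0)
  cl <- assign_step(centers)
  for (it in seq_len(config$max_kmeans_iter)) {
    new_centers <- centers
    for (k in seq_len(K)) {
      members <- cl == k
      if (any(members)) new_centers[k, ] <- colMeans(x[members, , drop = FALSE])
    }
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    cl <- assign_step(centers)
    wss <- 0
    for (k in seq_len(K)) {
      members <- cl == k
      if (any(members)) wss <- wss + sum(sweep(x[members, , drop = FALSE], 2, centers[k, ])^2)
    }
    wss_history <- c(wss_history, wss)
    if (shift < config$kmeans_tol) break
  }
  list(labels = matrix(cl - 1L, h, w), centroids = centers,
       wss_history = wss_history)
}

#' Remove the cluster nearest to white
#'
#' Identifies the cluster whose centroid has minimal Euclidean distance to
#' (255, 255, 255) and overwrites all its pixels with `fill`; other pixels are
#' untouched. Applying the operation twice is a no-op after the first pass
#' (the removed cluster is then uniformly `fill`).
#'
#' @param image H x W x 3 RGB array.
#' @param labels H x W integer cluster-id matrix (`0..K-1`).
#' @param centroids K x 3 centroid matrix.
#' @param fill RGB triple written over the removed cluster.
#' @return The edited RGB image.
#' @export
remove_white_cluster <- function(image, labels, centroids, fill = c(255, 255, 255)) {
  stopifnot(is_rgb(image), is.matrix(labels), is.matrix(centroids))
  d2white <- rowSums(sweep(centroids, 2, c(255, 255, 255))^2)
  target <- which.min(d2white) - 1L
  sel <- labels == target
  for (ch in 1:3) {
    v <- image[, , ch]
    v[sel] <- fill[ch]
    image[, , ch] <- v
  }
  image
}

#' Background-removal segmentation pipeline
#'
#' Hue normalisation and multi-level Otsu thresholding, hue posterisation back
#' to RGB, K-means colour clustering, and removal of the cluster nearest to
#' white. The output differs from the input only at removed-cluster pixels.
#'
#' @param image H x W x 3 RGB array in \[0, 255\].
#' @param config A [segmentation_config()].
#' @return A list: `image` (background-removed RGB), `removed_mask` (binary
#'   matrix of overwritten pixels), `kmeans` (clustering result),
#'   `thresholds` (hue thresholds).
#' @export
segment_image <- function(image, config = segmentation_config()) {
  thr <- hue_multilevel_threshold(image, config$n_hue_levels)
  # posterise hue to per-level means, keep saturation/value, back to RGB
  rgbv <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]), as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbv, maxColorValue = 255)
  lv <- as.vector(thr$labels)
  hue <- hsv[1, ]
  for (k in unique(lv)) hue[lv == k] <- mean(hsv[1, lv == k])
  hexcol <- grDevices::hsv(hue, hsv[2, ], hsv[3, ])
  post <- grDevices::col2rgb(hexcol)
  h <- dim(image)[1]; w <- dim(image)[2]
  posterised <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) posterised[, , ch] <- matrix(post[ch, ], h, w)
  km <- kmeans_color_segment(posterised, config)
  d2white <- rowSums(sweep(km$centroids, 2, c(255, 255, 255))^2)
  target <- which.min(d2white) - 1L
  removed_mask <- (km$labels == target) * 1L
  out <- image
  for (ch in 1:3) {
    v <- out[, , ch]
    v[removed_mask == 1L] <- config$white_fill[ch]
    out[, , ch] <- v
  }
  list(image = out, removed_mask = removed_mask, kmeans = km,
       thresholds = thr$thresholds)
}
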