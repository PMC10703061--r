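#' Wrapper-fitness configuration
#'
#' The wrapper cost of a feature subset is
#' `f = w * err + (1 - w) * |S| / D`, where `err` is the mean
#' misclassification rate of a k-nearest-neighbour classifier over seeded
#' stratified inner cross-validation restricted to the selected columns and
#' `|S|` the subset size. The empty subset is unusable, so its error is fixed
#' at 1. Lower is better.
#'
#' @param penalty_weight Error weight w in (0, 1], default 0.99.
#' @param knn_k Neighbourhood size of the inner k-NN classifier.
#' @param inner_folds Number of inner CV folds (>= 2).
#' @param seed Integer seed fixing the inner folds and k-NN tie-breaks.
#' @return A `fitness_config` list.
#' @export
fitness_config <- function(penalty_weight = 0.99, knn_k = 5L, inner_folds = 5L,
                           seed = 1L) {
  check_number(penalty_weight, "penalty_weight", min = 1e-12, max = 1)
  check_number(knn_k, "knn_k", min = 1, integer = TRUE)
  check_number(inner_folds, "inner_folds", min = 2, integer = TRUE)
  structure(list(penalty_weight = penalty_weight, knn_k = as.integer(knn_k),
                 inner_folds = as.integer(inner_folds), seed = as.integer(seed),
                 empty_subset_error = 1),
            class = "fitness_config")
}

# Stratified fold ids: within each class, a seeded shuffle is dealt round-robin
# into k folds, keeping class proportions near-equal across folds.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(factor(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Mean k-NN misclassification rate over precomputed folds; columns are
# standardised with training-fold statistics before distance computation.
knn_cv_error <- function(x, labels, folds, k, seed) {
  errs <- numeric(max(folds))
  with_seed(seed, {
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      mu <- colMeans(x[tr, , drop = FALSE])
      sdev <- apply(x[tr, , drop = FALSE], 2, sd)
      sdev[sdev == 0 | !is.finite(sdev)] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sdev, "/")
      xte <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, sdev, "/")
      kk <- min(k, nrow(xtr))
      pred <- class::knn(xtr, xte, labels[tr], k = kk)
      errs[f] <- mean(pred != labels[!tr])
    }
  })
  mean(errs)
}

#' Wrapper fitness of a feature subset
#'
#' @param bits Integer 0/1 vector of length D (1 = feature kept).
#' @param table A `feature_table` with at least two classes.
#' @param config A [fitness_config()].
#' @return The scalar cost `w * err + (1 - w) * |S| / D`.
#' @export
#' @examples
#' tab <- generate_feature_table(table_spec(n_samples = 40, n_features = 6,
#'                                          n_informative = 2, seed = 1))
#' wrapper_fitness(rep(1L, 6), tab, fitness_config())
wrapper_fitness <- function(bits, table, config = fitness_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (nlevels(droplevels(table$labels)) < 2) {
    stop("feature table must contain at least two classes")
  }
  D <- ncol(table$features)
  if (length(bits) != D) stop("bits length must equal the feature count")
  w <- config$penalty_weight
  size_frac <- sum(bits) / D
  if (sum(bits) == 0) {
    return(w * config$empty_subset_error)
  }
  folds <- stratified_folds(table$labels, config$inner_folds, config$seed)
  err <- knn_cv_error(table$features[, bits == 1L, drop = FALSE],
                      table$labels, folds, config$knn_k, config$seed)
  w * err + (1 - w) * size_frac
}
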