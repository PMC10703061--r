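#' Confusion counts and classification metrics
#'
#' Computes the confusion counts of a two-class prediction and the metric
#' suite: accuracy `(tp + tn) / n`, precision `tp / (tp + fp)`,
#' recall/sensitivity `tp / (tp + fn)`, specificity `tn / (tn + fp)` and the
#' F1 score `2 * P * R / (P + R)`. A metric with a zero denominator is
#' undefined and reported as `NA` (never an error), so that means over folds
#' can skip it explicitly.
#'
#' @param labels True class vector.
#' @param predictions Predicted class vector (same length).
#' @param positive_class The label counted as positive (default `"tumor"`).
#' @return A list with `counts` (`tp`, `tn`, `fp`, `fn`) and `metrics`
#'   (`accuracy`, `precision`, `recall`, `specificity`, `f1`, `NA` when
#'   undefined).
#' @export
#' @examples
#' classification_metrics(c("a", "a", "b"), c("a", "b", "b"), positive_class = "a")
classification_metrics <- function(labels, predictions, positive_class = "tumor") {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have equal length")
  }
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  pos <- labels == positive_class
  ppos <- predictions == positive_class
  tp <- sum(pos & ppos); tn <- sum(!pos & !ppos)
  fp <- sum(!pos & ppos); fn <- sum(pos & !ppos)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- if (is.na(precision) || is.na(recall) || (precision + recall) == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(
    counts = c(tp = tp, tn = tn, fp = fp, fn = fn),
    metrics = c(accuracy = safe_div(tp + tn, tp + tn + fp + fn),
                precision = precision, recall = recall,
                specificity = specificity, f1 = f1)
  )
}

#' k-nearest-neighbour classifier specification
#'
#' @param k Neighbourhood size.
#' @return A classifier spec usable by [kfold_cv()].
#' @export
knn_spec <- function(k = 5L) {
  check_number(k, "k", min = 1, integer = TRUE)
  structure(list(type = "knn", k = as.integer(k)), class = "classifier_spec")
}

classify <- function(spec, xtr, ytr, xte, seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  mu <- colMeans(xtr)
  sdev <- apply(xtr, 2, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  xtr <- sweep(sweep(xtr, 2, mu), 2, sdev, "/")
  xte <- sweep(sweep(xte, 2, mu), 2, sdev, "/")
  kk <- min(spec$k, nrow(xtr))
  with_seed(seed, as.character(class::knn(xtr, xte, ytr, k = kk)))
}

#' k-fold cross-validation
#'
#' Seeded shuffle into `k` near-equal folds (plain shuffled by default;
#' `stratified = TRUE` balances classes per fold). Each fold serves once as
#' the test set; the classifier is fit on the remainder. Per-fold metric
#' reports and their mean (over folds where each metric is defined) are
#' returned.
#'
#' @param table A `feature_table`.
#' @param classifier A [knn_spec()].
#' @param k Number of folds (>= 2, <= n).
#' @param seed Integer seed for the fold shuffle.
#' @param stratified Balance class proportions across folds.
#' @param positive_class Label treated as positive.
#' @return A list: `folds` (fold id per sample), `per_fold` (list of metric
#'   reports), `mean_metrics` (named vector, mean over defined folds),
#'   `n_defined` (folds contributing to each mean).
#' @export
kfold_cv <- function(table, classifier = knn_spec(), k = 10L, seed = 1L,
                     stratified = FALSE, positive_class = "tumor") {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$features)
  check_number(k, "k", min = 2, integer = TRUE)
  if (n < k) stop("need at least as many samples as folds")
  fold <- if (stratified) {
    stratified_folds(table$labels, k, seed)
  } else {
    with_seed(seed, {
      ord <- sample.int(n)
      f <- integer(n)
      f[ord] <- rep_len(seq_len(k), n)
      f
    })
  }
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    te <- fold == f
    pred <- classify(classifier, table$features[!te, , drop = FALSE],
                     table$labels[!te], table$features[te, , drop = FALSE],
                     seed = derive_seed(seed, f))
    per_fold[[f]] <- classification_metrics(table$labels[te], pred,
                                            positive_class = positive_class)
  }
  mets <- do.call(rbind, lapply(per_fold, function(p) p$metrics))
  mean_metrics <- colMeans(mets, na.rm = TRUE)
  n_defined <- colSums(!is.na(mets))
  mean_metrics[n_defined == 0] <- NA_real_
  list(folds = fold, per_fold = per_fold, mean_metrics = mean_metrics,
       n_defined = n_defined)
}

#' Train/validation/test split plan
#'
#' Seeded shuffle followed by contiguous slicing: validation and test sizes
#' are the rounded fractions, training receives the remainder. The three
#' index sets are disjoint and cover `1..n`.
#'
#' @param n Number of samples (>= 3).
#' @param fractions Length-3 fractions `(train, validation, test)` summing to
#'   1; default `c(0.70, 0.15, 0.15)`.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train`, `validation`, `test`
#'   and the echoed `fractions` and `seed`.
#' @export
train_val_test_split <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  check_number(n, "n", min = 3, integer = TRUE)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9) {
    stop_invalid("fractions", "must be three values summing to 1")
  }
  n_val <- round(n * fractions[2])
  n_test <- round(n * fractions[3])
  n_train <- n - n_val - n_test
  if (n_train < 1) stop_invalid("fractions", "leave no training samples")
  ord <- with_seed(seed, sample.int(n))
  list(train = sort(ord[seq_len(n_train)]),
       validation = sort(ord[n_train + seq_len(n_val)]),
       test = sort(ord[n_train + n_val + seq_len(n_test)]),
       fractions = fractions, seed = as.integer(seed))
}
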