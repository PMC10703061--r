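#' Specification for a synthetic feature table
#'
#' Describes a two-class feature table with a known subset of informative
#' columns among pure-noise columns. Informative columns are drawn
#' class-conditionally with means separated by `effect_size * noise_sigma`
#' (a standardised shift of `effect_size` sigma units); noise columns are
#' class-independent.
#'
#' @param n_samples Number of rows (>= 2).
#' @param n_features Total number of feature columns D.
#' @param n_informative Number of class-informative columns k, 0 < k <= D.
#' @param effect_size Standardised mean shift between classes, sigma units.
#' @param noise_sigma Within-class standard deviation (> 0).
#' @param class_balance Fraction of tumour-labelled rows, in (0, 1).
#' @param seed Integer seed.
#' @return An object of class `synthetic_table_spec`.
#' @export
table_spec <- function(n_samples = 200, n_features = 50, n_informative = 5,
                       effect_size = 2, noise_sigma = 1, class_balance = 0.5,
                       seed = 1L) {
  check_number(n_samples, "n_samples", min = 2, integer = TRUE)
  check_number(n_features, "n_features", min = 1, integer = TRUE)
  check_number(n_informative, "n_informative", min = 1, integer = TRUE)
  if (n_informative > n_features) {
    stop_invalid("n_informative", "must not exceed n_features")
  }
  check_number(effect_size, "effect_size", min = 0)
  check_number(noise_sigma, "noise_sigma", min = 1e-12)
  check_number(class_balance, "class_balance", min = 1e-9, max = 1 - 1e-9)
  check_number(seed, "seed", integer = TRUE)
  structure(list(
    n_samples = as.integer(n_samples), n_features = as.integer(n_features),
    n_informative = as.integer(n_informative), effect_size = effect_size,
    noise_sigma = noise_sigma, class_balance = class_balance,
    seed = as.integer(seed)
  ), class = "synthetic_table_spec")
}

new_feature_table <- function(features, labels, informative = NULL) {
  stopifnot(is.matrix(features), length(labels) == nrow(features))
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%03d", seq_len(ncol(features)))
  }
  structure(list(
    features = features,
    labels = factor(labels, levels = c("healthy", "tumor")),
    informative = informative
  ), class = "feature_table")
}

#' Generate a synthetic two-class feature table
#'
#' @param spec A [table_spec()] object.
#' @return A `feature_table`: `features` (n x D numeric matrix), `labels`
#'   (factor with levels healthy/tumor) and `informative` (logical length-D
#'   ground-truth mask with exactly `n_informative` `TRUE` entries).
#' @export
#' @examples
#' tab <- generate_feature_table(table_spec(n_samples = 20, n_features = 8,
#'                                          n_informative = 2, seed = 3))
#' sum(tab$informative)
generate_feature_table <- function(spec) {
  if (!inherits(spec, "synthetic_table_spec")) {
    stop_invalid("spec", "must be created by table_spec()")
  }
  n <- spec$n_samples; d <- spec$n_features; k <- spec$n_informative
  n_tumor <- round(n * spec$class_balance)
  with_seed(spec$seed, {
    labels <- sample(c(rep("tumor", n_tumor), rep("healthy", n - n_tumor)))
    info_idx <- sort(sample.int(d, k))
    x <- matrix(rnorm(n * d, sd = spec$noise_sigma), n, d)
    shift <- spec$effect_size * spec$noise_sigma
    is_tumor <- labels == "tumor"
    for (j in info_idx) {
      x[is_tumor, j] <- x[is_tumor, j] + shift / 2
      x[!is_tumor, j] <- x[!is_tumor, j] - shift / 2
    }
    informative <- rep(FALSE, d)
    informative[info_idx] <- TRUE
    new_feature_table(x, labels, informative)
  })
}

#' Write and read feature tables as CSV
#'
#' The CSV carries one column per feature plus a final `label` column. For
#' synthetic tables the ground-truth informative column names are written to
#' a sidecar CSV `<path>.informative.csv`.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$features)
  df$label <- as.character(table$labels)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(table$informative)) {
    write.csv(data.frame(informative = colnames(table$features)[table$informative]),
              paste0(path, ".informative.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("CSV must contain a `label` column")
  labels <- df$label
  df$label <- NULL
  info <- NULL
  sidecar <- paste0(path, ".informative.csv")
  if (file.exists(sidecar)) {
    nm <- read.csv(sidecar)$informative
    info <- names(df) %in% nm
  }
  new_feature_table(as.matrix(df), labels, info)
}
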