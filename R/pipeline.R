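#' End-to-end pipeline configuration
#'
#' Bundles the stage toggles and nested module configurations of the full
#' screening pipeline. All nested configs are validated at construction, so a
#' run fails before any stage executes if a parameter is out of range.
#'
#' Segmentation defaults to off on the feature path: the handcrafted and
#' filter-bank extractors operate on the preprocessed image directly, and
#' background removal is only needed when downstream analysis requires it.
#'
#' @param n_images Number of synthetic images to generate.
#' @param tumor_fraction Fraction of tumour-labelled images.
#' @param image A [image_spec()] for the synthetic stage.
#' @param n_spots,spot_radius Specular spots stamped per image before
#'   preprocessing (0 disables).
#' @param median_window Median-filter window (odd).
#' @param inpaint An [inpaint_config()].
#' @param segment Run the segmentation stage.
#' @param segmentation A [segmentation_config()].
#' @param glcm A [glcm_config()].
#' @param conv A [conv_config()].
#' @param aoa An [aoa_config()] for feature selection.
#' @param fitness A [fitness_config()].
#' @param eval_folds Outer cross-validation folds for the final report.
#' @param split_fractions Train/validation/test fractions.
#' @param seed Global seed; stage seeds are derived from it.
#' @param out_dir Optional directory for artifacts (CSV table, JSON report).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_images = 40L, tumor_fraction = 0.5,
                            image = image_spec(width = 64, height = 64),
                            n_spots = 2L, spot_radius = 3,
                            median_window = 3L,
                            inpaint = inpaint_config(),
                            segment = FALSE,
                            segmentation = segmentation_config(),
                            glcm = glcm_config(),
                            conv = conv_config(pool = 15L),
                            aoa = aoa_config(population_size = 10L,
                                             max_iterations = 30L),
                            fitness = fitness_config(inner_folds = 4L,
                                                     knn_k = 3L),
                            eval_folds = 10L, split_fractions = c(0.7, 0.15, 0.15),
                            seed = 1L, out_dir = NULL) {
  check_number(n_images, "n_images", min = 4, integer = TRUE)
  check_number(tumor_fraction, "tumor_fraction", min = 0, max = 1)
  stopifnot(inherits(image, "synthetic_image_spec"),
            inherits(inpaint, "inpaint_config"),
            inherits(segmentation, "segmentation_config"),
            inherits(glcm, "glcm_config"), inherits(conv, "conv_config"),
            inherits(aoa, "aoa_config"), inherits(fitness, "fitness_config"))
  check_number(median_window, "median_window", min = 3, integer = TRUE)
  check_number(eval_folds, "eval_folds", min = 2, integer = TRUE)
  structure(list(n_images = as.integer(n_images), tumor_fraction = tumor_fraction,
                 image = image, n_spots = as.integer(n_spots),
                 spot_radius = spot_radius, median_window = as.integer(median_window),
                 inpaint = inpaint, segment = isTRUE(segment),
                 segmentation = segmentation, glcm = glcm, conv = conv,
                 aoa = aoa, fitness = fitness, eval_folds = as.integer(eval_folds),
                 split_fractions = split_fractions, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the end-to-end screening pipeline
#'
#' Executes synth -> preprocess (spots, inpainting, median filter) ->
#' optional segmentation -> feature extraction (handcrafted GLCM + conv
#' filter bank) -> fusion -> wrapper feature selection (binary AOA) ->
#' evaluation (k-fold CV and 70/15/15 split on the selected subset). Every
#' stage is seeded from the global seed; two runs with the same config
#' produce identical reports.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit per-stage progress messages with timings.
#' @return A report list: per-stage parameters, selected features, fitness
#'   history, cross-validated and held-out metrics. When `config$out_dir` is
#'   set, the fused table (CSV) and the report (JSON) are written there.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("stage %-11s %6.2fs", name, proc.time()[["elapsed"]] - t0)
    res
  }

  images <- stage("synth", generate_image_dataset(
    config$image, config$n_images, config$tumor_fraction, seed = config$seed))

  images <- stage("preprocess", lapply(seq_along(images), function(i) {
    im <- images[[i]]
    if (config$n_spots > 0) {
      sp <- add_light_spots(im, config$n_spots, config$spot_radius,
                            seed = derive_seed(config$seed, 100000L + i))
      im <- sp$image
      im$pixels <- inpaint_diffusion(im$pixels, sp$mask, config$inpaint)
    }
    im$pixels <- median_filter(im$pixels, config$median_window)
    im
  }))

  if (config$segment) {
    images <- stage("segment", lapply(images, function(im) {
      seg <- segment_image(im$pixels, config$segmentation)
      im$pixels <- seg$image
      im
    }))
  }

  table <- stage("extract", {
    rows <- lapply(images, function(im) {
      hc <- handcrafted_features(im$pixels, config$glcm)
      cv <- conv_filterbank_features(im$pixels, config$conv)
      fuse_features(hc, cv)
    })
    feats <- do.call(rbind, rows)
    new_feature_table(feats, vapply(images, `[[`, "", "label"))
  })

  sel <- stage("select", {
    aoa <- config$aoa
    aoa$seed <- derive_seed(config$seed, 3L)
    fitc <- config$fitness
    fitc$seed <- derive_seed(config$seed, 4L)
    optimize_selection(table, aoa, fitc)
  })

  report <- stage("evaluate", {
    keep <- sel$best_bits == 1L
    sub <- new_feature_table(table$features[, keep, drop = FALSE], table$labels)
    cv <- kfold_cv(sub, knn_spec(config$fitness$knn_k), k = config$eval_folds,
                   seed = derive_seed(config$seed, 5L))
    split <- train_val_test_split(nrow(sub$features), config$split_fractions,
                                  seed = derive_seed(config$seed, 6L))
    pred <- classify(knn_spec(config$fitness$knn_k),
                     sub$features[split$train, , drop = FALSE],
                     sub$labels[split$train],
                     sub$features[split$test, , drop = FALSE],
                     seed = derive_seed(config$seed, 7L))
    holdout <- classification_metrics(sub$labels[split$test], pred)
    list(
      seed = config$seed,
      n_images = config$n_images,
      image_size = c(config$image$height, config$image$width),
      segmented = config$segment,
      n_features_handcrafted = 4L * length(config$glcm$offsets),
      n_features_conv = ncol(table$features) - 4L * length(config$glcm$offsets),
      n_features_fused = ncol(table$features),
      selection = list(
        mode = config$aoa$update_mode, kind = config$aoa$transfer_kind,
        n_selected = sum(keep), mask = sel$best_bits,
        selected = sel$selected, best_fitness = sel$best_fitness,
        history = sel$history, n_evaluations = sel$n_evaluations
      ),
      cv = list(k = config$eval_folds, mean_metrics = as.list(cv$mean_metrics),
                n_defined = as.list(cv$n_defined)),
      holdout = list(fractions = config$split_fractions,
                     counts = as.list(holdout$counts),
                     metrics = as.list(holdout$metrics))
    )
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(table, file.path(config$out_dir, "features.csv"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
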