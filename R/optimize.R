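#' Binary AOA wrapper feature selection
#'
#' Runs the binary Arithmetic Optimization Algorithm over feature subsets of
#' `table`, scoring candidates with [wrapper_fitness()] (minimised).
#'
#' In `transfer` mode the continuous population is initialised by the uniform
#' rule, every coordinate of every individual is updated toward the elite by
#' the division/multiplication (exploration) and subtraction/addition
#' (exploitation) operators scheduled by MOA/MOP, and positions are converted
#' to bits by the S- or V-shaped transfer rule ([binarize_position()]); the
#' elite bit string, embedded at its box corner, serves as the attractor. In
#' `literal` mode each individual hill-climbs with the literal moves
#' ([literal_neighbor()]): single-bit flip (S) or XOR with a sparse random
#' vector (V), accepting only strict improvements (the fitness here is a cost,
#' so acceptance is `f_new < f_current`).
#'
#' Both modes are elitist: the best-so-far solution and fitness are tracked
#' and the recorded history is non-increasing. Identical seeds give identical
#' results; fitness values are cached per bit string, so `n_evaluations`
#' counts distinct subsets evaluated.
#'
#' @param table A `feature_table`.
#' @param aoa An [aoa_config()].
#' @param fit A [fitness_config()].
#' @param fitness Optional custom fitness `function(bits)` (minimised);
#'   defaults to the k-NN wrapper cost on `table`. When supplied, `table` may
#'   be `NULL` and `D` must be given.
#' @param D Problem dimension; defaults to the table's feature count.
#' @return An `optimization_result`: `best_bits`, `best_fitness`,
#'   `selected` (names of kept features, when a table is given), `history`
#'   (elite fitness, length `max_iterations + 1`), `n_evaluations`, `seed`,
#'   and the config echoes.
#' @export
optimize_selection <- function(table, aoa = aoa_config(), fit = fitness_config(),
                               fitness = NULL, D = NULL) {
  if (is.null(fitness)) {
    stopifnot(inherits(table, "feature_table"))
    D <- ncol(table$features)
    fitness <- function(bits) wrapper_fitness(bits, table, fit)
  }
  check_number(D, "D", min = 1, integer = TRUE)

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_bits <- function(bits) {
    key <- paste(bits, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    val <- fitness(bits)
    cache[[key]] <- val
    val
  }

  M <- aoa$population_size
  N_i <- aoa$max_iterations
  lb <- aoa$lower_bound; ub <- aoa$upper_bound
  center <- (lb + ub) / 2
  kind <- aoa$transfer_kind

  with_seed(aoa$seed, {
    X <- matrix(lb + runif(M * D) * (ub - lb), M, D)
    B <- matrix(as.integer(X > center), M, D)
    fitv <- apply(B, 1, eval_bits)
    ei <- which.min(fitv)   # stable: earliest index wins ties
    best_bits <- B[ei, ]
    best_fit <- fitv[ei]
    history <- best_fit

    if (aoa$update_mode == "transfer") {
      mag <- (ub - lb) * aoa$mu + lb
      for (t in seq_len(N_i)) {
        moa <- moa_value(t, aoa)
        mop <- mop_value(t, aoa)
        # elite bits embedded at their box corner act as Best(x)
        bx <- matrix(lb + best_bits * (ub - lb), M, D, byrow = TRUE)
        r1 <- matrix(runif(M * D), M, D)
        r2 <- matrix(runif(M * D), M, D)
        explore <- r1 > moa
        Xn <- ifelse(explore,
                     ifelse(r2 < 0.5, bx / (mop + aoa$epsilon) * mag,
                            bx * mop * mag),
                     ifelse(r2 < 0.5, bx - mop * mag, bx + mop * mag))
        Xn <- clip(Xn, lb, ub)
        rb <- matrix(runif(M * D), M, D)
        if (kind == "S") {
          arg <- aoa$transfer_gain / (ub - lb) * (Xn - center)
          Bn <- matrix(as.integer(rb < transfer_probability(arg, "S")), M, D)
        } else {
          corner <- lb + B * (ub - lb)
          arg <- aoa$transfer_gain / (ub - lb) * (Xn - corner)
          flip <- rb < transfer_probability(arg, "V")
          Bn <- matrix(as.integer(ifelse(flip, 1L - B, B)), M, D)
        }
        X <- Xn
        B <- Bn
        fitv <- apply(B, 1, eval_bits)
        ei <- which.min(fitv)
        if (fitv[ei] < best_fit) {   # strict: earlier elite retained on ties
          best_fit <- fitv[ei]
          best_bits <- B[ei, ]
        }
        history <- c(history, best_fit)
      }
    } else {
      p_flip <- if (is.null(aoa$p_flip)) 1 / D else aoa$p_flip
      for (t in seq_len(N_i)) {
        for (m in seq_len(M)) {
          cand <- literal_neighbor(B[m, ], kind, p_flip)
          f_new <- eval_bits(cand)
          if (f_new < fitv[m]) {   # cost: accept strict improvements only
            B[m, ] <- cand
            fitv[m] <- f_new
            if (f_new < best_fit) {
              best_fit <- f_new
              best_bits <- cand
            }
          }
        }
        history <- c(history, best_fit)
      }
    }

    selected <- if (!is.null(table)) colnames(table$features)[best_bits == 1L] else NULL
    structure(list(
      best_bits = best_bits, best_fitness = best_fit, selected = selected,
      history = history, n_evaluations = n_eval, seed = aoa$seed,
      aoa_config = aoa, fitness_config = if (is.null(table)) NULL else fit
    ), class = "optimization_result")
  })
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Binary AOA result (%s mode, kind %s)\n",
              x$aoa_config$update_mode, x$aoa_config$transfer_kind))
  cat(sprintf("  best fitness : %.6f\n", x$best_fitness))
  cat(sprintf("  bits kept    : %d / %d\n", sum(x$best_bits), length(x$best_bits)))
  cat(sprintf("  evaluations  : %d (distinct subsets)\n", x$n_evaluations))
  invisible(x)
}
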