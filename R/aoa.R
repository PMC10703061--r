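#' Arithmetic Optimization Algorithm configuration
#'
#' Parameters of the continuous Arithmetic Optimization Algorithm (AOA) and
#' of its two binarizations. The math-optimizer-accelerated probability (MOA)
#' schedules the explore/exploit switch linearly between `moa_min` and
#' `moa_max`; the math-optimizer probability (MOP) scales the operator
#' magnitude as `1 - (t/T)^(1/alpha)`. Exploration uses the division and
#' multiplication operators, exploitation subtraction and addition, all
#' centred on the best solution found so far.
#'
#' In the binary variants the elite is a bit string; its continuous embedding
#' (each bit at the corresponding `lower`/`upper` corner of the box) serves as
#' the `Best(x)` of the update operators, and a transfer function converts the
#' proposed coordinates back into bits. The transfer argument is the
#' coordinate mapped affinely around the box centre and scaled by
#' `transfer_gain`, so that the S-shaped sigmoid (and V-shaped `|tanh|`) can
#' both saturate and express either bit value; kind-specific default gains
#' (S: 5, V: 8) span the functions' effective domain.
#'
#' @param population_size Number of candidate solutions M (>= 2).
#' @param max_iterations Iteration budget N_i (>= 1).
#' @param moa_min,moa_max MOA endpoints, `0 <= moa_min < moa_max <= 1`.
#' @param mu Search-control constant of the operator magnitude (default 0.499).
#' @param alpha Exploitation-sensitivity exponent of MOP (default 5).
#' @param epsilon Small positive constant guarding the division operator.
#' @param lower_bound,upper_bound Per-dimension box bounds (scalars).
#' @param update_mode `"transfer"` (continuous AOA + transfer binarization) or
#'   `"literal"` (bit-flip / XOR hill-climbing moves).
#' @param transfer_kind `"S"` (sigmoid resampling) or `"V"` (|tanh|-driven
#'   bit flips).
#' @param transfer_gain Scaling of the transfer argument; `NULL` selects the
#'   kind-specific default (S: 5, V: 8).
#' @param p_flip Per-bit flip probability of the literal V move (`NULL` =
#'   `1/D`).
#' @param seed Integer seed; every random draw of a run flows from it.
#' @return An `aoa_config` list.
#' @export
aoa_config <- function(population_size = 20L, max_iterations = 100L,
                       moa_min = 0.2, moa_max = 0.9, mu = 0.499, alpha = 5,
                       epsilon = 1e-6, lower_bound = 0, upper_bound = 1,
                       update_mode = c("transfer", "literal"),
                       transfer_kind = c("S", "V"), transfer_gain = NULL,
                       p_flip = NULL, seed = 1L) {
  check_number(population_size, "population_size", min = 2, integer = TRUE)
  check_number(max_iterations, "max_iterations", min = 1, integer = TRUE)
  check_number(moa_min, "moa_min", min = 0, max = 1 - 1e-12)
  check_number(moa_max, "moa_max", min = 0, max = 1)
  if (moa_min >= moa_max) stop_invalid("moa_max", "must exceed moa_min")
  check_number(mu, "mu", min = 0)
  check_number(alpha, "alpha", min = 1e-9)
  check_number(epsilon, "epsilon", min = 1e-300)
  if (lower_bound >= upper_bound) stop_invalid("upper_bound", "must exceed lower_bound")
  update_mode <- match.arg(update_mode)
  transfer_kind <- match.arg(transfer_kind)
  if (is.null(transfer_gain)) {
    transfer_gain <- if (transfer_kind == "S") 5 else 8
  }
  check_number(transfer_gain, "transfer_gain", min = 1e-9)
  structure(list(
    population_size = as.integer(population_size),
    max_iterations = as.integer(max_iterations),
    moa_min = moa_min, moa_max = moa_max, mu = mu, alpha = alpha,
    epsilon = epsilon, lower_bound = lower_bound, upper_bound = upper_bound,
    update_mode = update_mode, transfer_kind = transfer_kind,
    transfer_gain = transfer_gain, p_flip = p_flip, seed = as.integer(seed)
  ), class = "aoa_config")
}

#' Initialise a continuous AOA population
#'
#' Each coordinate is drawn independently as
#' `x = lower + s * (upper - lower)` with `s ~ U(0, 1)`.
#'
#' @param config An [aoa_config()].
#' @param D Problem dimension (>= 1).
#' @return An M x D numeric matrix of positions.
#' @export
init_population <- function(config, D) {
  check_number(D, "D", min = 1, integer = TRUE)
  M <- config$population_size
  with_seed(config$seed, {
    matrix(config$lower_bound +
             runif(M * D) * (config$upper_bound - config$lower_bound), M, D)
  })
}

#' Math-optimizer-accelerated (MOA) probability
#'
#' Linear schedule `Min + L_i * (Max - Min) / N_i` deciding between
#' exploration (`r1 > MOA`) and exploitation.
#'
#' @param L_i Current iteration, `0 <= L_i <= N_i`.
#' @param config An [aoa_config()].
#' @return The MOA value.
#' @export
moa_value <- function(L_i, config) {
  N_i <- config$max_iterations
  check_number(L_i, "L_i", min = 0, max = N_i)
  config$moa_min + L_i * (config$moa_max - config$moa_min) / N_i
}

#' Math-optimizer probability (MOP)
#'
#' Operator-magnitude schedule `1 - L_i^(1/alpha) / N_i^(1/alpha)`, monotone
#' non-increasing in the iteration.
#'
#' @inheritParams moa_value
#' @return The MOP value in \[0, 1\].
#' @export
mop_value <- function(L_i, config) {
  check_number(L_i, "L_i", min = 0)
  1 - L_i^(1 / config$alpha) / config$max_iterations^(1 / config$alpha)
}

#' One AOA coordinate update
#'
#' Exploration (`r1 > moa`): division `best / (mop + eps) * mag` if
#' `r2 < 0.5`, else multiplication `best * mop * mag`. Exploitation:
#' subtraction `best - mop * mag` if `r3 < 0.5`, else addition
#' `best + mop * mag`; `mag = (ub - lb) * mu + lb`. The result is clipped to
#' the box.
#'
#' @param best_coord Coordinate of the best solution.
#' @param moa,mop Current schedule values.
#' @param config An [aoa_config()].
#' @param r Optional numeric vector `c(r1, r2)` of the branch draws
#'   (`r2` doubles as the division/multiplication and subtraction/addition
#'   selector); drawn from the RNG when `NULL`.
#' @return The updated, clipped coordinate.
#' @export
aoa_position_update <- function(best_coord, moa, mop, config, r = NULL) {
  if (is.null(r)) r <- runif(2)
  lb <- config$lower_bound; ub <- config$upper_bound
  mag <- (ub - lb) * config$mu + lb
  x <- if (r[1] > moa) {
    if (r[2] < 0.5) best_coord / (mop + config$epsilon) * mag
    else best_coord * mop * mag
  } else {
    if (r[2] < 0.5) best_coord - mop * mag
    else best_coord + mop * mag
  }
  clip(x, lb, ub)
}

#' S- and V-shaped transfer functions
#'
#' `S(x) = 1 / (1 + exp(-x))` and `V(x) = |tanh(x)|`, mapping a real argument
#' to a probability in \[0, 1\].
#'
#' @param x Numeric argument (vectorised).
#' @param kind `"S"` or `"V"`.
#' @return Probabilities in \[0, 1\].
#' @export
transfer_probability <- function(x, kind = c("S", "V")) {
  kind <- match.arg(kind)
  if (kind == "S") 1 / (1 + exp(-x)) else abs(tanh(x))
}

# Map coordinates onto the transfer function's argument scale: the box is
# centred and scaled so its ends land at +/- gain/2.
transfer_argument <- function(coords, config) {
  center <- (config$lower_bound + config$upper_bound) / 2
  config$transfer_gain / (config$upper_bound - config$lower_bound) * (coords - center)
}

#' Binarize a continuous position
#'
#' S rule: each bit is resampled as 1 with probability `S(arg)`, where `arg`
#' is the coordinate mapped through [transfer_argument()] (box centre maps to
#' probability 0.5, the upper corner saturates towards 1). V rule
#' (velocity-style): the flip probability is `V` of the scaled displacement
#' between the coordinate and the corner encoding the current bit, so a
#' coordinate sitting at its bit's corner keeps the bit and a coordinate at
#' the opposite corner almost surely flips it toward agreement.
#'
#' @param position Numeric coordinate vector within the box.
#' @param kind `"S"` or `"V"`.
#' @param current_bits Integer 0/1 vector of the same length (the solution
#'   being updated; required by the V rule).
#' @param config An [aoa_config()].
#' @return Integer 0/1 vector.
#' @export
binarize_position <- function(position, kind, current_bits, config) {
  if (length(position) != length(current_bits)) {
    stop("position and current_bits lengths differ")
  }
  r <- runif(length(position))
  if (kind == "S") {
    as.integer(r < transfer_probability(transfer_argument(position, config), "S"))
  } else {
    corner <- config$lower_bound +
      current_bits * (config$upper_bound - config$lower_bound)
    arg <- config$transfer_gain /
      (config$upper_bound - config$lower_bound) * (position - corner)
    flip <- r < transfer_probability(arg, "V")
    as.integer(ifelse(flip, 1L - current_bits, current_bits))
  }
}

#' Literal hill-climbing neighbour moves
#'
#' The literal binary moves: for `"S"`, exactly one uniformly chosen bit is
#' flipped; for `"V"`, the bits are XOR-ed with a random vector whose entries
#' are 1 with probability `p_flip` (default `1/D`), redrawn until at least one
#' bit flips.
#'
#' @param bits Integer 0/1 vector.
#' @param kind `"S"` or `"V"`.
#' @param p_flip Per-bit flip probability for the V move (`NULL` = `1/D`).
#' @return The neighbouring 0/1 vector (same length).
#' @export
literal_neighbor <- function(bits, kind = c("S", "V"), p_flip = NULL) {
  kind <- match.arg(kind)
  D <- length(bits)
  stopifnot(D >= 1)
  if (kind == "S") {
    b <- sample.int(D, 1L)
    bits[b] <- 1L - bits[b]
    bits
  } else {
    if (is.null(p_flip)) p_flip <- 1 / D
    repeat {
      v <- as.integer(runif(D) < p_flip)
      if (any(v == 1L)) break
    }
    as.integer(bitwXor(as.integer(bits), v))
  }
}
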