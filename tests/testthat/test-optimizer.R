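test_that("MOA and MOP schedules hit their analytic endpoints", {
  cfg <- aoa_config(max_iterations = 100, moa_min = 0.2, moa_max = 0.9)
  expect_equal(moa_value(0, cfg), 0.2)
  expect_equal(moa_value(100, cfg), 0.9)
  expect_equal(moa_value(50, cfg), 0.55)
  expect_error(moa_value(101, cfg), "L_i")

  expect_equal(mop_value(100, cfg), 0)
  lin <- aoa_config(max_iterations = 100, alpha = 1)
  expect_equal(mop_value(50, lin), 0.5)
  mops <- vapply(1:100, mop_value, numeric(1), config = cfg)
  expect_true(all(diff(mops) <= 0))
})

test_that("population initialisation is uniform in the box and seeded", {
  cfg <- aoa_config(population_size = 5, seed = 8)
  P <- init_population(cfg, 12)
  expect_equal(dim(P), c(5, 12))
  expect_true(all(P >= 0 & P <= 1))
  expect_identical(P, init_population(cfg, 12))
  expect_error(init_population(cfg, 0), "D")

  degen <- aoa_config(lower_bound = 0.5, upper_bound = 0.5 + 1e-12, seed = 1)
  expect_true(all(abs(init_population(degen, 4) - 0.5) < 1e-9))
})

test_that("position updates follow the four arithmetic operators and stay in the box", {
  cfg <- aoa_config(mu = 0.499, epsilon = 1e-6)
  # division branch: r1 > moa (explore), r2 < 0.5
  expect_equal(aoa_position_update(0.5, moa = 0.3, mop = 0.5, cfg, r = c(0.9, 0.2)),
               0.5 / (0.5 + 1e-6) * 0.499, tolerance = 1e-12)
  # multiplication branch
  expect_equal(aoa_position_update(0.5, moa = 0.3, mop = 0.5, cfg, r = c(0.9, 0.8)),
               0.5 * 0.5 * 0.499, tolerance = 1e-12)
  # subtraction / addition branches
  expect_equal(aoa_position_update(0.5, moa = 0.9, mop = 0.5, cfg, r = c(0.1, 0.2)),
               0.5 - 0.5 * 0.499, tolerance = 1e-12)
  expect_equal(aoa_position_update(0.5, moa = 0.9, mop = 0.5, cfg, r = c(0.1, 0.8)),
               0.5 + 0.5 * 0.499, tolerance = 1e-12)
  # clipping
  set.seed(4)
  for (i in 1:50) {
    x <- aoa_position_update(runif(1), moa = runif(1), mop = runif(1), cfg)
    expect_true(x >= 0 && x <= 1)
  }
})

test_that("transfer functions are the sigmoid and |tanh| with their symmetries", {
  expect_equal(transfer_probability(0, "S"), 0.5)
  expect_equal(transfer_probability(0, "V"), 0)
  g <- seq(-6, 6, by = 0.05)
  expect_true(all(diff(transfer_probability(g, "S")) > 0))
  expect_equal(transfer_probability(g, "V"), transfer_probability(-g, "V"))
  expect_true(all(transfer_probability(g, "S") >= 0 & transfer_probability(g, "S") <= 1))
  expect_true(all(transfer_probability(g, "V") >= 0 & transfer_probability(g, "V") <= 1))
})

test_that("binarization saturates, preserves corners, and matches its probability", {
  cfg <- aoa_config(transfer_kind = "S")
  # coordinates at the upper corner are (essentially) always kept as 1
  set.seed(1)
  bits <- replicate(200, binarize_position(rep(1, 4), "S", rep(0L, 4), cfg))
  expect_gte(mean(bits), transfer_probability(cfg$transfer_gain / 2, "S") - 0.05)

  # V rule: a coordinate at its current bit's corner never flips the bit
  cfgv <- aoa_config(transfer_kind = "V")
  cur <- c(1L, 0L, 1L, 0L)
  pos <- c(1, 0, 1, 0)   # each coordinate sits at its bit's corner
  set.seed(2)
  for (i in 1:20) expect_identical(binarize_position(pos, "V", cur, cfgv), cur)

  # Monte-Carlo: empirical bit frequency matches the transfer probability
  coord <- 0.65
  p <- transfer_probability(rbscreen:::transfer_argument(coord, cfg), "S")
  set.seed(3)
  draws <- replicate(10000, binarize_position(coord, "S", 0L, cfg))
  expect_lt(abs(mean(draws) - p), 0.02)

  expect_error(binarize_position(c(0.5, 0.5), "S", 0L, cfg), "length")
})

test_that("literal neighbour moves flip exactly as specified", {
  set.seed(9)
  for (i in 1:20) {
    bits <- as.integer(runif(12) < 0.5)
    s_move <- literal_neighbor(bits, "S")
    expect_equal(sum(s_move != bits), 1)
    v_move <- literal_neighbor(bits, "V")
    expect_length(v_move, 12)
    expect_gte(sum(v_move != bits), 1)
  }
  expect_equal(as.integer(bitwXor(c(1L, 0L, 1L, 0L), c(0L, 1L, 1L, 0L))),
               c(1L, 1L, 0L, 0L))
})

test_that("wrapper fitness rewards informative subsets and penalises size", {
  # perfectly separable table: two far-apart Gaussian classes
  set.seed(5)
  n <- 40
  x <- rbind(matrix(rnorm(20 * 3, mean = 0, sd = 0.1), 20, 3),
             matrix(rnorm(20 * 3, mean = 10, sd = 0.1), 20, 3))
  tab <- rbscreen:::new_feature_table(x, rep(c("healthy", "tumor"), each = 20))
  fitc <- fitness_config(penalty_weight = 0.99, knn_k = 1, seed = 2)
  expect_equal(wrapper_fitness(rep(1L, 3), tab, fitc), 0.01, tolerance = 1e-12)
  expect_equal(wrapper_fitness(rep(0L, 3), tab, fitc), 0.99, tolerance = 1e-12)

  # informative-only subset beats an equally sized noise-only subset
  st <- generate_feature_table(table_spec(n_samples = 120, n_features = 20,
                                          n_informative = 4, effect_size = 2,
                                          seed = 7))
  fit2 <- fitness_config(seed = 7)
  info_bits <- as.integer(st$informative)
  noise_idx <- head(which(!st$informative), 4)
  noise_bits <- integer(20); noise_bits[noise_idx] <- 1L
  expect_lt(wrapper_fitness(info_bits, st, fit2),
            wrapper_fitness(noise_bits, st, fit2))

  single <- rbscreen:::new_feature_table(x, rep("healthy", 40))
  expect_error(wrapper_fitness(rep(1L, 3), single, fitc), "two classes")
})

test_that("both update modes are elitist, seeded, and solve a small OneMax", {
  onemax <- function(bits) 1 - sum(bits) / length(bits)
  for (mode in c("transfer", "literal")) {
    for (kind in c("S", "V")) {
      cfg <- aoa_config(population_size = 10, max_iterations = 60,
                        update_mode = mode, transfer_kind = kind, seed = 11)
      res <- optimize_selection(NULL, cfg, fitness = function(b) onemax(b), D = 10)
      expect_true(all(diff(res$history) <= 0))
      expect_length(res$history, 61)
      expect_lte(res$best_fitness, 0.1)
      res2 <- optimize_selection(NULL, cfg, fitness = function(b) onemax(b), D = 10)
      expect_identical(res$best_bits, res2$best_bits)
      expect_identical(res$history, res2$history)
    }
  }
})

test_that("literal mode only ever accepts strict improvements", {
  # a fitness that records every evaluation lets us replay acceptance
  calls <- new.env(); calls$log <- list()
  f <- function(bits) {
    val <- 1 - sum(bits) / length(bits)
    calls$log[[length(calls$log) + 1L]] <- list(bits = bits, val = val)
    val
  }
  cfg <- aoa_config(population_size = 4, max_iterations = 30,
                    update_mode = "literal", transfer_kind = "S", seed = 3)
  res <- optimize_selection(NULL, cfg, fitness = f, D = 8)
  expect_true(all(diff(res$history) <= 0))
  # the returned best is genuinely the minimum of everything evaluated
  vals <- vapply(calls$log, `[[`, numeric(1), "val")
  expect_equal(res$best_fitness, min(vals))
})
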