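test_that("gray quantisation bins uniformly with 255 in the top bin", {
  expect_equal(quantize_gray(matrix(c(0, 255, 127, 128), 2, 2), 2),
               matrix(c(0L, 1L, 0L, 1L), 2, 2))
  expect_equal(quantize_gray(matrix(90, 3, 3), 8), matrix(2L, 3, 3))
  set.seed(5)
  img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  q <- quantize_gray(img, 7)
  # per-pixel binning oracle
  expect_equal(as.vector(q), pmin(floor(as.vector(img) * 7 / 256), 6))
})

test_that("GLCM counting matches direct pair enumeration", {
  img <- matrix(c(0L, 0L, 1L,
                  0L, 1L, 1L,
                  1L, 1L, 2L), 3, 3, byrow = TRUE)
  cfg <- glcm_config(levels = 3, symmetric = FALSE, normalize = FALSE)
  C <- compute_glcm(img, c(0, 1), cfg)$matrix
  expect_equal(C, matrix(c(1, 2, 0,
                           0, 2, 1,
                           0, 0, 0), 3, 3, byrow = TRUE))

  const <- matrix(2L, 5, 5)
  Cc <- compute_glcm(const, c(0, 1), glcm_config(levels = 4, symmetric = FALSE,
                                                 normalize = FALSE))$matrix
  expect_equal(Cc[3, 3], 5 * 4)
  expect_equal(sum(Cc), 20)

  expect_error(compute_glcm(matrix(5L, 3, 3), c(0, 1), glcm_config(levels = 4)),
               "quantize")

  set.seed(99)
  for (i in 1:20) {
    im <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    off <- sample(list(c(0, 1), c(1, 0), c(1, 1), c(1, -1), c(0, 2)), 1)[[1]]
    asym <- compute_glcm(im, off, glcm_config(levels = 4, symmetric = FALSE,
                                              normalize = FALSE))$matrix
    sym <- compute_glcm(im, off, glcm_config(levels = 4, symmetric = TRUE,
                                             normalize = FALSE))$matrix
    expect_equal(sym, asym + t(asym))
  }
})

test_that("Haralick statistics reproduce analytic 2x2 cases", {
  single <- matrix(c(1, 0, 0, 0), 2, 2)
  s <- glcm_statistics(single)
  expect_equal(as.numeric(s[c("contrast", "energy", "homogeneity")]), c(0, 1, 1),
               tolerance = 1e-12)
  expect_equal(as.numeric(s["correlation"]), 0)
  expect_true(attr(s, "degenerate"))

  diag2 <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  d <- glcm_statistics(diag2)
  expect_equal(as.numeric(d), c(0, 1, 0.5, 1), tolerance = 1e-12)
  expect_false(attr(d, "degenerate"))

  anti <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  a <- glcm_statistics(anti)
  expect_equal(as.numeric(a), c(1, -1, 0.5, 0.5), tolerance = 1e-12)

  expect_error(glcm_statistics(matrix(c(2, 0, 0, 1), 2, 2)), "normalized")
})

test_that("handcrafted features are stable, named, and transpose-consistent", {
  im <- generate_fundus_image(image_spec(width = 48, height = 48, seed = 6), "tumor")
  v <- handcrafted_features(im$pixels)
  expect_length(v, 16)
  expect_true(all(is.finite(v)))
  expect_identical(v, handcrafted_features(im$pixels))

  # statistics in their analytic ranges
  expect_true(all(v[grepl("contrast", names(v))] >= 0))
  expect_true(all(v[grepl("energy", names(v))] > 0 & v[grepl("energy", names(v))] <= 1))
  expect_true(all(abs(v[grepl("correlation", names(v))]) <= 1 + 1e-12))

  # pair counting commutes with transposition: offset (0,1) on I == (1,0) on t(I)
  g <- rbscreen:::to_gray(im$pixels)
  cfg <- glcm_config(levels = 8, offsets = list(c(0, 1)))
  cfg_t <- glcm_config(levels = 8, offsets = list(c(1, 0)))
  expect_equal(unname(handcrafted_features(g, cfg)),
               unname(handcrafted_features(t(g), cfg_t)), tolerance = 1e-12)
})

test_that("the conv filter bank equals the nested-loop oracle and respects ReLU", {
  set.seed(17)
  img <- matrix(runif(64, 0, 255), 8, 8)
  kern <- matrix(rnorm(9), 3, 3)
  cfg <- conv_config(n_filters = 1, kernel = 3, pool = 2, kernels = list(kern),
                     bias = 0.1)
  got <- conv_filterbank_features(img, cfg)
  want <- oracle_conv_relu_pool(img / 255, kern, 0.1, 2)
  expect_equal(unname(got), as.vector(want), tolerance = 1e-12)
  expect_true(all(got >= 0))

  zero <- conv_filterbank_features(matrix(0, 10, 10), conv_config(seed = 2))
  expect_true(all(zero == 0))

  # repeat the oracle across random kernels
  for (i in 1:20) {
    im2 <- matrix(runif(100, 0, 255), 10, 10)
    k2 <- matrix(rnorm(9), 3, 3)
    c2 <- conv_config(n_filters = 1, kernel = 3, pool = 3, kernels = list(k2))
    expect_equal(unname(conv_filterbank_features(im2, c2)),
                 as.vector(oracle_conv_relu_pool(im2 / 255, k2, 0, 3)),
                 tolerance = 1e-12)
  }

  expect_error(conv_filterbank_features(matrix(0, 6, 6),
                                        conv_config(pool = 10)), "pool")
})

test_that("brightening never decreases nonnegative-kernel filter-bank outputs", {
  set.seed(23)
  kerns <- lapply(1:4, function(i) matrix(runif(9, 0, 0.5), 3, 3))
  cfg <- conv_config(n_filters = 4, kernel = 3, pool = 2, kernels = kerns)
  img <- matrix(runif(144, 0, 200), 12, 12)
  dim_out <- conv_filterbank_features(img, cfg)
  brighter <- conv_filterbank_features(pmin(img + 30, 255), cfg)
  expect_true(all(brighter >= dim_out - 1e-12))
})

test_that("feature fusion preserves order and rejects name collisions", {
  a <- c(x1 = 1, x2 = 2)
  b <- c(y1 = 3)
  f <- fuse_features(a, b)
  expect_length(f, 3)
  expect_equal(f[1:2], a)
  expect_identical(fuse_features(a, numeric(0)), a)
  expect_identical(fuse_features(numeric(0), b), b)
  expect_error(fuse_features(a, c(x1 = 9)), "collision")
})
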