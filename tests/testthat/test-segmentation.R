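test_that("hue thresholds maximise between-class variance (oracle check)", {
  # three well-separated constant-hue regions
  labels <- matrix(1L, 12, 12)
  labels[, 5:8] <- 2L; labels[, 9:12] <- 3L
  px <- rgb_from_labels(labels, list(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255)))
  res <- hue_multilevel_threshold(px, 3)
  for (k in 1:3) {
    expect_equal(length(unique(res$labels[labels == k])), 1)
  }
  # regions get distinct level ids
  expect_equal(length(unique(c(res$labels[labels == 1][1], res$labels[labels == 2][1],
                               res$labels[labels == 3][1]))), 3)

  # constant hue collapses to a single label
  flat <- rgb_from_labels(matrix(1L, 8, 8), list(c(200, 60, 60)))
  expect_equal(length(unique(as.vector(hue_multilevel_threshold(flat, 3)$labels))), 1)

  expect_error(hue_multilevel_threshold(matrix(1, 5, 5), 3), "RGB")

  # threshold pair equals the exhaustive oracle on a 16-bin histogram
  set.seed(11)
  counts <- rpois(16, lambda = c(rep(40, 5), rep(2, 6), rep(30, 5)))
  expect_equal(rbscreen:::otsu_multilevel_thresholds(counts, 3),
               oracle_otsu_2thresholds(counts))
})

test_that("k-means colour segmentation recovers constructed clusters", {
  cfg <- segmentation_config(K = 1, seed = 2)
  px <- rgb_from_labels(matrix(sample(1:2, 64, replace = TRUE), 8, 8),
                        list(c(10, 10, 10), c(240, 240, 240)))
  one <- kmeans_color_segment(px, cfg)
  expect_true(all(one$labels == 0L))
  expect_equal(as.vector(one$centroids),
               c(mean(px[, , 1]), mean(px[, , 2]), mean(px[, , 3])))

  # three well-separated colour blobs -> near-perfect agreement
  set.seed(77)
  truth <- matrix(sample(1:3, 400, replace = TRUE), 20, 20)
  px3 <- rgb_from_labels(truth, list(c(250, 200, 210), c(60, 90, 220), c(250, 250, 250)))
  px3 <- px3 + array(rnorm(1200, sd = 2), dim = dim(px3))
  cfg3 <- segmentation_config(K = 3, seed = 5)
  km <- kmeans_color_segment(px3, cfg3)
  expect_gte(adjusted_rand_index(as.vector(km$labels), as.vector(truth)), 0.99)

  # determinism and non-increasing within-cluster sum of squares
  expect_identical(km$labels, kmeans_color_segment(px3, cfg3)$labels)
  expect_true(all(diff(km$wss_history) <= 1e-6))

  # every pixel carries exactly one contiguous id
  expect_setequal(unique(as.vector(km$labels)), 0:2)

  expect_error(kmeans_color_segment(rgb_from_labels(matrix(1L, 4, 4),
                                                    list(c(1, 2, 3))),
                                    segmentation_config(K = 3)), "distinct")
})

test_that("k-means agrees with the reference Lloyd implementation from the same start", {
  set.seed(31)
  truth <- matrix(sample(1:3, 225, replace = TRUE), 15, 15)
  px <- rgb_from_labels(truth, list(c(200, 40, 60), c(30, 180, 90), c(240, 240, 240)))
  px <- px + array(rnorm(675, sd = 3), dim = dim(px))
  cfg <- segmentation_config(K = 3, seed = 9, kmeans_tol = 1e-10)
  km <- kmeans_color_segment(px, cfg)
  x <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  init <- rbscreen:::farthest_point_init(x, 3, 9)
  ref <- suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100,
                                        algorithm = "Lloyd"))
  expect_gte(adjusted_rand_index(as.vector(km$labels), ref$cluster), 0.999)
  expect_equal(km$centroids[order(km$centroids[, 1]), ],
               ref$centers[order(ref$centers[, 1]), ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("white-cluster removal targets the centroid nearest white and is idempotent", {
  truth <- matrix(sample(1:3, 144, replace = TRUE), 12, 12)
  px <- rgb_from_labels(truth, list(c(250, 200, 210), c(60, 90, 220), c(252, 252, 252)))
  cfg <- segmentation_config(K = 3, seed = 1)
  km <- kmeans_color_segment(px, cfg)
  d2w <- rowSums(sweep(km$centroids, 2, c(255, 255, 255))^2)
  white_id <- which.min(d2w) - 1L
  # identified cluster is the truly white one
  maj <- as.vector(km$labels)[as.vector(truth) == 3]
  expect_equal(white_id, as.integer(names(sort(table(maj), decreasing = TRUE))[1]))

  out <- remove_white_cluster(px, km$labels, km$centroids, fill = c(0, 0, 0))
  sel <- km$labels == white_id
  for (ch in 1:3) {
    expect_true(all(out[, , ch][sel] == 0))
    expect_equal(out[, , ch][!sel], px[, , ch][!sel])
  }
  # second application on the already-filled image changes nothing
  out2 <- remove_white_cluster(out, km$labels, km$centroids, fill = c(0, 0, 0))
  expect_identical(out, out2)
})

test_that("the segmentation pipeline removes the background and nothing else", {
  # white slide background with two tissue colours
  truth <- matrix(1L, 16, 16)
  truth[4:9, 3:8] <- 2L; truth[10:14, 9:15] <- 3L
  px <- rgb_from_labels(truth, list(c(251, 251, 251), c(230, 120, 160), c(70, 90, 200)))
  cfg <- segmentation_config(K = 3, seed = 6)
  seg <- segment_image(px, cfg)
  expect_identical(seg$image, segment_image(px, cfg)$image)

  # output differs from input only at removed pixels
  diffpx <- apply(abs(seg$image - px), c(1, 2), max)
  expect_true(all(which(diffpx > 0) %in% which(seg$removed_mask == 1L)))

  # background (cluster nearest white) was filled; tissue colours survive
  expect_gte(mean(seg$removed_mask[truth == 1L]), 0.95)
  expect_true(all(seg$removed_mask[truth == 2L] == 0))
  expect_true(all(seg$removed_mask[truth == 3L] == 0))
})
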