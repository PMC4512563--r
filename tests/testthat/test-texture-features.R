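test_that("sum/difference images follow the displacement definition", {
  cst <- sum_difference_images(matrix(5, 8, 8), c(2, 1))
  expect_true(all(cst$S == 10))
  expect_true(all(cst$D == 0))

  p <- matrix(c(1, 3, 2, 4), 2, 2)   # [[1,2],[3,4]] in row terms
  sd01 <- sum_difference_images(p, c(0, 1))
  expect_equal(sd01$S[, 1], c(3, 7))
  expect_equal(sd01$D[, 1], c(-1, -1))

  ## antisymmetry of D on the interior overlap: with g = f shifted by +d,
  ## D_{-d}(g) = -D_{+d}(f) wherever neither uses replicated borders
  set.seed(10)
  m <- matrix(runif(100), 10, 10)
  fwd <- sum_difference_images(m, c(1, 2))
  shifted <- m[c(2:10, 10), c(3:10, 10, 10)]
  bwd <- sum_difference_images(shifted, c(-1, -2))
  expect_equal(fwd$D[2:9, 3:8], -bwd$D[2:9, 3:8])

  expect_error(sum_difference_images(m, c(10, 0)))
})

test_that("local histograms are normalized integer-binned probabilities", {
  cst <- sum_difference_images(matrix(5, 4, 4), c(1, 1))
  h <- local_histograms(cst)
  expect_equal(unname(h$probs_sum["10"]), 1)

  pr <- structure(list(S = matrix(c(2, 2, 4, 6), 2, 2),
                       D = matrix(0, 2, 2), displacement = c(0L, 0L)),
                  class = "sumdiff_pair")
  h2 <- local_histograms(pr)
  expect_equal(unname(h2$probs_sum[c("2", "4", "6")]), c(0.5, 0.25, 0.25))
  expect_equal(h2$N, 4L)

  set.seed(11)
  rp <- sum_difference_images(matrix(sample(0:255, 64, TRUE), 8, 8), c(1, 0))
  h3 <- local_histograms(rp)
  expect_equal(sum(h3$probs_sum), 1, tolerance = 1e-12)
  expect_equal(sum(h3$probs_diff), 1, tolerance = 1e-12)

  expect_error(local_histograms(rp, matrix(FALSE, 8, 8)), "empty")
})

test_that("constant input collapses the features to their analytic values", {
  pr <- sum_difference_images(matrix(42, 16, 16), c(3, 3))
  fm <- unser_feature_maps(pr, radius = 3, features = 1:8)
  expect_true(all(abs(fm$f1 - 42) < 1e-9))
  expect_true(all(abs(fm$f2) < 1e-9))
  expect_true(all(abs(fm$f3) < 1e-9))   # zero difference image zeroes the product
  expect_true(all(abs(fm$f5) < 1e-9))
  expect_true(all(abs(fm$f6 - 1) < 1e-9))
  expect_true(all(abs(fm$f7) < 1e-9))
  expect_true(all(abs(fm$f8) < 1e-9))
})

test_that("filtered feature maps equal the naive per-pixel disk oracle", {
  set.seed(12)
  plane <- matrix(runif(32 * 32, 0, 255), 32, 32)
  pr <- sum_difference_images(plane, c(3, 3))
  fast <- unser_feature_maps(pr, radius = 3, features = 1:8)
  slow <- naive_unser(pr$S, pr$D, radius = 3, features = 1:8)
  for (f in paste0("f", 1:8)) {
    denom <- pmax(abs(slow[[f]]), 1)
    expect_lt(max(abs(fast[[f]] - slow[[f]]) / denom), 1e-9)
  }
  expect_error(unser_feature_maps(pr, radius = 3, features = 9))
})

test_that("feature maps are translation-equivariant on the interior", {
  set.seed(13)
  plane <- matrix(runif(40 * 40, 0, 10), 40, 40)
  shifted <- rbind(plane[-1, ], plane[40, ])   # shift up by one row
  f1 <- unser_feature_maps(sum_difference_images(plane, c(1, 1)), radius = 3,
                           features = 5)$f5
  f2 <- unser_feature_maps(sum_difference_images(shifted, c(1, 1)), radius = 3,
                           features = 5)$f5
  expect_equal(f1[7:38, 6:35], f2[6:37, 6:35], tolerance = 1e-9)
})

test_that("the feature bank has 64 layers with the block-wise indexing", {
  set.seed(14)
  img <- rgb_image(array(sample(0:255, 48 * 48 * 3, TRUE), c(48, 48, 3)))
  bank <- build_feature_bank(img, radius = 10)
  expect_length(bank$maps, 64L)
  expect_equal(bank$index$channel[3], "R")
  expect_equal(bank$index$feature[3], "Energy")
  expect_equal(bank$index$channel[5], "R")
  expect_equal(bank$index$feature[5], "Contrast")
  expect_equal(bank$index$channel[63], "K")
  expect_equal(bank$index$feature[63], "Cluster shade")

  cst <- build_feature_bank(flat_image(48, 48, 120), radius = 10)
  varlayers <- bank$index$layer[bank$index$feature_id %in% c(2L, 5L)]
  for (l in varlayers) expect_true(all(abs(cst$maps[[l]]) < 1e-9))

  expect_error(build_feature_bank(flat_image(12, 12, 1), radius = 10), "small")
})

test_that("a brighter constant image yields a strictly larger mean map", {
  dim_img <- build_feature_bank(flat_image(44, 44, 50), radius = 10)
  bright <- build_feature_bank(flat_image(44, 44, 200), radius = 10)
  expect_true(all(bright$maps[[1]] > dim_img$maps[[1]]))
})

test_that("Fisher ranking scores and orders features correctly", {
  ## feature 1 identical across classes -> score 0, ranked last;
  ## feature 2 built for J = (0-1)^2 / (0.5+0.5) = 1 exactly
  X <- cbind(rep(1, 4), c(-0.5, 0.5, 0.5, 1.5))
  lab <- c("a", "a", "b", "b")
  rk <- fisher_rank(X, lab)
  expect_equal(rk$feature, c(2L, 1L))
  expect_equal(rk$score[1], 1)
  expect_equal(rk$score[2], 0)

  expect_error(fisher_rank(X, c("a", "a", "a", "a")))

  set.seed(15)
  X2 <- matrix(rnorm(40 * 6), 40, 6)
  lab2 <- rep(c("a", "b"), each = 20)
  rk2 <- fisher_rank(X2, lab2)
  expect_equal(sort(rk2$feature), 1:6)
  expect_true(all(diff(rk2$score) <= 0))
})

test_that("select_features takes a stable prefix of the ranking", {
  rk <- data.frame(feature = c(4L, 2L, 1L, 3L), score = c(3, 2, 1, 0))
  expect_equal(select_features(rk, 0), integer(0))
  expect_equal(select_features(rk, 4), c(4L, 2L, 1L, 3L))
  expect_equal(select_features(rk, 2), c(4L, 2L))
  expect_error(select_features(rk, 5))
})

test_that("the shipped retained-feature set has 25 distinct in-range indices", {
  sel <- default_selected_features()
  expect_length(sel, 25L)
  expect_equal(anyDuplicated(sel), 0L)
  expect_true(all(sel >= 1 & sel <= 64))
})
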