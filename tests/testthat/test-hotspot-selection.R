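test_that("the dispersion penalty reproduces its closed-form values", {
  expect_equal(dispersion_penalty(c(0, 0), NULL, rho = 0.2, fov_width = 10), 1)
  expect_equal(dispersion_penalty(c(0, 0), matrix(c(0, 10), 1), rho = 0.2,
                                  fov_width = 10), 0.8)
  sel <- matrix(c(0, 10, 0, 20), 2, byrow = TRUE)
  expect_equal(dispersion_penalty(c(0, 0), sel, rho = 0.2, fov_width = 10), 0.7)

  ## bounded by 1 and decreasing as a selected field approaches
  set.seed(50)
  for (i in 1:20) {
    cand <- runif(2, 0, 100)
    s <- matrix(runif(6, 0, 100), 3, 2)
    p <- dispersion_penalty(cand, s, rho = 0.2, fov_width = 10)
    expect_lte(p, 1)
  }
  far <- dispersion_penalty(c(0, 0), matrix(c(0, 50), 1), 0.2, 10)
  near <- dispersion_penalty(c(0, 0), matrix(c(0, 12), 1), 0.2, 10)
  expect_gt(far, near)
  expect_error(dispersion_penalty(c(1, 1), matrix(c(1, 1), 1), 0.2, 10),
               "coincides")
})

test_that("density maps conserve mark mass", {
  shape <- c(120, 120)
  zero <- density_map(list(centroids = matrix(numeric(0), 0, 2),
                           marks = array(FALSE, shape)), fov_width = 20)
  expect_true(all(zero$values == 0))

  one <- density_map(list(centroids = matrix(c(60, 60), 1),
                          marks = array(FALSE, shape)), fov_width = 20)
  expect_equal(sum(one$values), 1, tolerance = 1e-6)

  ## a mark near the border still contributes exactly 1
  edge <- density_map(list(centroids = matrix(c(2, 2), 1),
                           marks = array(FALSE, shape)), fov_width = 20)
  expect_equal(sum(edge$values), 1, tolerance = 1e-6)

  ## two far-apart equal clusters give two equal local maxima
  cen <- rbind(matrix(c(30, 30), 10, 2, byrow = TRUE),
               matrix(c(90, 90), 10, 2, byrow = TRUE))
  two <- density_map(list(centroids = cen, marks = array(FALSE, shape)),
                     fov_width = 20)
  expect_equal(sum(two$values), 20, tolerance = 1e-6)
  expect_equal(two$values[31, 31], two$values[91, 91], tolerance = 1e-9)
  expect_gt(two$values[31, 31], two$values[61, 61])
})

## all-tissue map plus a density field assembled from mark clusters
toy_scene <- function(shape = c(160, 160), centers, n_each = 30, sd = 4,
                      fov = 24, seed = 51) {
  set.seed(seed)
  cen <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_each, centers[i, 1], sd), rnorm(i * 0 + n_each, centers[i, 2], sd))))
  dmap <- density_map(list(centroids = cen, marks = array(FALSE, shape)),
                      fov_width = fov)
  map <- structure(list(mask = matrix(TRUE, shape[1], shape[2]),
                        working_downsample = 1L, provenance = "toy"),
                   class = "specimen_map")
  list(dmap = dmap, map = map, fov = fov)
}

test_that("rho > 0 disperses fields relative to rho = 0 on a single peak", {
  sc <- toy_scene(centers = matrix(c(80, 80), 1), n_each = 120, sd = 10)
  s0 <- select_fields(sc$dmap, sc$map, n = 20, rho = 0, fov_width = sc$fov,
                      tumor_cover = 0.8, stride = 2)
  s2 <- select_fields(sc$dmap, sc$map, n = 20, rho = 0.2, fov_width = sc$fov,
                      tumor_cover = 0.8, stride = 2)
  pd <- function(s) mean(dist(as.matrix(s$fields[, c("center_row", "center_col")])))
  expect_gt(nrow(s0$fields), 5)
  expect_gt(pd(s2), pd(s0))
})

test_that("two equal hot spots each receive one of two fields", {
  sc <- toy_scene(centers = rbind(c(40, 40), c(120, 120)), n_each = 40, sd = 5)
  s <- select_fields(sc$dmap, sc$map, n = 2, rho = 0.2, fov_width = sc$fov,
                     stride = 2)
  f <- s$fields
  expect_equal(nrow(f), 2L)
  d1 <- sqrt((f$center_row - 40)^2 + (f$center_col - 40)^2)
  d2 <- sqrt((f$center_row - 120)^2 + (f$center_col - 120)^2)
  expect_true(any(d1 < sc$fov) && any(d2 < sc$fov))
})

test_that("selections respect overlap and coverage constraints", {
  sc <- toy_scene(centers = rbind(c(50, 60), c(110, 100)), n_each = 60, sd = 12)
  ## carve out a glass corner: fields there fail the coverage rule
  sc$map$mask[1:60, 1:60] <- FALSE
  s <- select_fields(sc$dmap, sc$map, n = 20, rho = 0.2, fov_width = sc$fov,
                     tumor_cover = 0.8, stride = 2)
  f <- s$fields
  expect_gt(nrow(f), 2)
  for (i in seq_len(nrow(f) - 1)) for (j in (i + 1):nrow(f)) {
    ov <- ki67hotspot:::rect_overlap_frac(f$center_row[i] - f$center_row[j],
                                          f$center_col[i] - f$center_col[j],
                                          sc$fov, sc$fov)
    expect_lte(ov, 0.5)
  }
  ## coverage >= 0.8 for every field
  for (i in seq_len(nrow(f))) {
    rr <- round(f$center_row[i] + 1 + seq(-sc$fov / 2, sc$fov / 2 - 1))
    cc <- round(f$center_col[i] + 1 + seq(-sc$fov / 2, sc$fov / 2 - 1))
    expect_gte(mean(sc$map$mask[rr, cc]), 0.8)
  }
  ## empty density -> no fields, with a warning
  zero <- density_map(list(centroids = matrix(numeric(0), 0, 2),
                           marks = array(FALSE, c(160, 160))), fov_width = 24)
  expect_warning(s0 <- select_fields(zero, sc$map, n = 5, rho = 0.2,
                                     fov_width = 24), "eligible")
  expect_equal(nrow(s0$fields), 0L)
})

test_that("rho calibration scans the grid and returns its minimizer", {
  sc <- toy_scene(centers = rbind(c(40, 40), c(120, 120)), n_each = 40, sd = 5)
  ref <- select_fields(sc$dmap, sc$map, n = 10, rho = 0.2, fov_width = sc$fov,
                       stride = 2)
  reffs <- observer_fieldset(as.matrix(ref$fields[, c("center_row", "center_col")]),
                             rep(10, nrow(ref$fields)), slide_id = "toy")
  slides <- list(list(dmap = sc$dmap, map = sc$map, reference = reffs))

  single <- calibrate_rho(slides, rho_grid = 0.3, fov_width = sc$fov,
                          n = 10, stride = 2)
  expect_equal(single$rho_star, 0.3)
  expect_equal(nrow(single$curve), 1L)

  grid <- seq(0.1, 0.3, by = 0.1)
  res <- calibrate_rho(slides, rho_grid = grid, fov_width = sc$fov,
                       n = 10, stride = 2)
  expect_equal(nrow(res$curve), length(grid))
  expect_equal(res$rho_star, res$curve$rho[which.min(res$curve$mean_lcm)])
  expect_error(calibrate_rho(slides, rho_grid = numeric(0), fov_width = 24))
})
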