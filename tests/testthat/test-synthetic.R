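test_that("slide generation is bit-identical under a fixed seed", {
  p <- fixture_small_params(seed = 9L)
  a <- generate_slide(p)
  b <- generate_slide(p)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  expect_identical(a$truth$hotspot_centers, b$truth$hotspot_centers)
})

test_that("planted fractions propagate into the nucleus table", {
  p0 <- synth_params(slide_size = c(700L, 700L), tissue_blob_count = 1L,
                     tissue_radius = c(250, 280), hotspot_count = 0L,
                     hemorrhage_count = 0L, ki67_background_pct = 0,
                     ki67_hotspot_pct = 0, seed = 12L)
  sl0 <- generate_slide(p0)
  expect_false(any(sl0$truth$nuclei$class == "pos"))

  sl <- fixture_slide()
  frac <- mean(sl$truth$nuclei$class == "pos")
  ## overall positive fraction between background and hot-spot levels
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.15)
  ## masks align with the raster
  expect_equal(dim(sl$truth$tissue_mask), dim(sl$image$pixels)[1:2])
  ## hemorrhage carries no nuclei
  nuc <- sl$truth$nuclei
  idx <- cbind(pmin(pmax(round(nuc$row) + 1, 1), nrow(sl$truth$hemorrhage_mask)),
               pmin(pmax(round(nuc$col) + 1, 1), ncol(sl$truth$hemorrhage_mask)))
  expect_equal(sum(sl$truth$hemorrhage_mask[idx]), 0)
})

test_that("without hot spots the nucleus pattern is homogeneous over tissue", {
  p <- synth_params(slide_size = c(900L, 900L), tissue_blob_count = 1L,
                    tissue_radius = c(400, 400), hotspot_count = 0L,
                    hemorrhage_count = 0L, seed = 31L)
  sl <- generate_slide(p)
  ## quadrats inside the single section: find its bounding center
  tm <- sl$truth$tissue_mask
  rows <- which(rowSums(tm) > 0); cols <- which(colSums(tm) > 0)
  cr <- mean(range(rows)); cc <- mean(range(cols))
  half <- 250
  nuc <- sl$truth$nuclei
  inside <- nuc$row > cr - half & nuc$row < cr + half &
            nuc$col > cc - half & nuc$col < cc + half
  qr <- floor((nuc$row[inside] - (cr - half)) / (2 * half / 5))
  qc <- floor((nuc$col[inside] - (cc - half)) / (2 * half / 5))
  counts <- table(factor(qr * 5 + qc, levels = 0:24))
  ## chi-square quadrat test of homogeneity at alpha = 0.01
  pval <- suppressWarnings(chisq.test(as.numeric(counts))$p.value)
  expect_gt(pval, 0.01)
})

test_that("generated fields carry exact ground truth and render audit counts", {
  z <- generate_field(n_pos = 0, n_neg = 0, seed = 2)
  expect_equal(z$count$total, 0L)

  gf <- generate_field(n_pos = 40, n_neg = 60, seed = 8)
  expect_equal(gf$count$positive, 40L)
  expect_equal(100 * gf$count$positive / gf$count$total, 40)

  ## noiseless render: connected components equal the requested count
  gq <- generate_field(n_pos = 12, n_neg = 18, noise_sigma = 0, seed = 13)
  dec <- stain_deconvolve(gq$image)
  lab <- EBImage::bwlabel(((dec$H > 0.4) | (dec$DAB > 0.4)) * 1)
  expect_equal(max(lab), 30)

  expect_error(generate_field(width = 32, height = 32, n_pos = 300, n_neg = 300,
                              seed = 1), "cannot place")
})

test_that("observer proxies honor jitter, dropout, and planted indices", {
  sl <- fixture_slide()
  ds <- fixture_params()$working_downsample
  exact <- generate_observer_proxy(sl$truth, working_downsample = ds,
                                   jitter_px = 0, dropout_frac = 0,
                                   ki67_noise_sd = 0, seed = 5)
  expect_equal(as.matrix(exact$fields[, c("row", "col")]),
               unname(sl$truth$hotspot_centers / ds), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(exact$fields$ki67_pct == sl$truth$ki67_hotspot_pct))

  ## dropout is binomial thinning
  p <- synth_params(seed = 44L)
  kept <- vapply(1:30, function(s) {
    tryCatch(nrow(generate_observer_proxy(sl$truth, ds, jitter_px = 0,
                                          dropout_frac = 0.5, seed = s)$fields),
             error = function(e) 0)   # all fields dropped
  }, numeric(1))
  expect_gt(mean(kept), 1)
  expect_lt(mean(kept), 3.5)
  expect_error(generate_observer_proxy(sl$truth, ds, dropout_frac = 0.999,
                                       seed = 1))
})

test_that("ground-truth helpers agree with the planted structure", {
  sl <- fixture_slide()
  p <- fixture_params()
  ds <- p$working_downsample
  dm <- truth_density_map(sl$truth, ds, fov_width = p$fov[2] / ds)
  npos <- sum(sl$truth$nuclei$class == "pos")
  expect_equal(sum(dm$values), npos, tolerance = 1e-6)
  ## density peaks near the hot spots
  hs <- sl$truth$hotspot_centers / ds
  athot <- mean(dm$values[round(hs) + 1])
  expect_gt(athot, 3 * mean(dm$values[dm$values > 0]))

  tm <- truth_specimen_map(sl$truth, ds)
  expect_s3_class(tm, "specimen_map")
  expect_equal(dim(tm$mask), dim(dm$values))

  ref <- truth_reference_selection(sl$truth, ds, fov_width = p$fov[2] / ds,
                                   n = 10)
  expect_s3_class(ref, "observer_fieldset")
  expect_gt(nrow(ref$fields), 5)
  expect_true(all(ref$fields$ki67_pct %in%
                  c(p$ki67_background_pct, p$ki67_hotspot_pct)))
})
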