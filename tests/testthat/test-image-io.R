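test_that("read_region crops exactly and adjacent regions tile their union", {
  set.seed(1)
  px <- array(sample(0:255, 100 * 100 * 3, replace = TRUE), c(100, 100, 3))
  img <- rgb_image(px, mpp_x = 0.5)

  full <- read_region(img, field_geometry(0, 0, 100, 100))
  expect_identical(full$pixels, px)

  tl <- read_region(img, field_geometry(0, 0, 10, 10))
  expect_identical(tl$pixels, px[1:10, 1:10, , drop = FALSE])

  a <- read_region(img, field_geometry(10, 20, 15, 30))
  b <- read_region(img, field_geometry(40, 20, 15, 30))
  whole <- read_region(img, field_geometry(10, 20, 15, 60))
  expect_identical(rbind(a$pixels[, , 1], b$pixels[, , 1]), whole$pixels[, , 1])

  expect_error(read_region(img, field_geometry(95, 0, 10, 10)), "bounds")
})

test_that("downsample is a block mean with ceiling dims and scaled mpp", {
  img <- flat_image(16, 16, 37)
  d8 <- downsample(img, 8)
  expect_equal(dim(d8), c(2L, 2L))
  expect_true(all(d8$pixels == 37))
  expect_equal(d8$downsample, 8L)

  ## 2x2-block checkerboard: every block holds two 0s and two 255s
  chk <- matrix(0, 16, 16)
  chk[(row(chk) + col(chk)) %% 2 == 0] <- 255
  dc <- downsample(rgb_image(array(chk, c(16, 16, 3))), 2)
  expect_true(all(abs(dc$pixels - 127.5) < 1e-9))

  expect_identical(downsample(img, 1), img)
  expect_error(downsample(img, 0))

  ## ceiling dims for non-divisible sizes
  d3 <- downsample(flat_image(10, 11, 5), 3)
  expect_equal(dim(d3), c(4L, 4L))
})

test_that("crop-then-downsample equals downsample-then-crop on aligned rects", {
  set.seed(2)
  img <- rgb_image(array(sample(0:255, 64 * 64 * 3, TRUE), c(64, 64, 3)))
  a <- downsample(read_region(img, field_geometry(16, 32, 32, 32)), 4)
  b <- read_region(downsample(img, 4), field_geometry(16, 32, 8, 8, level_downsample = 4))
  expect_equal(a$pixels, b$pixels)
})

test_that("rgb_to_cmyk follows the naive device formulas with the K=1 guard", {
  img <- rgb_image(array(rep(c(255, 0, 255, 255, 0, 0, 255, 0, 0),
                             each = 1), c(3, 1, 3)))
  ## pixels: white (255,255,255), black (0,0,0), red (255,0,0)
  cmyk <- rgb_to_cmyk(img)
  expect_equal(unname(c(cmyk$C[1, 1], cmyk$M[1, 1], cmyk$Y[1, 1], cmyk$K[1, 1])),
               c(0, 0, 0, 0))
  expect_equal(unname(c(cmyk$C[2, 1], cmyk$M[2, 1], cmyk$Y[2, 1], cmyk$K[2, 1])),
               c(0, 0, 0, 1))
  expect_equal(unname(c(cmyk$C[3, 1], cmyk$M[3, 1], cmyk$Y[3, 1], cmyk$K[3, 1])),
               c(0, 1, 1, 0))
  set.seed(3)
  rnd <- rgb_image(array(sample(0:255, 30, TRUE), c(2, 5, 3)))
  out <- rgb_to_cmyk(rnd)
  for (p in out) expect_true(all(p >= 0 & p <= 1))
})

test_that("u* plane follows reference colorimetry anchors", {
  img <- rgb_image(array(c(0, 255, 255, 0,   0, 255, 0, 0,   0, 255, 0, 255),
                         c(4, 1, 3)))
  ## pixels: black, D65 white, saturated red, saturated blue
  u <- rgb_to_luv_u(img)
  expect_equal(u[1, 1], 0)
  expect_lt(abs(u[2, 1]), 1e-6)
  expect_gt(u[3, 1], 0)
  expect_gt(u[3, 1], u[4, 1])
})

test_that("combined u+C normalizes each plane then sums", {
  expect_equal(combined_u_plus_c(matrix(5, 3, 3), matrix(2, 3, 3)),
               matrix(0, 3, 3))
  set.seed(4)
  u <- matrix(runif(20, -10, 40), 4, 5)
  expect_equal(combined_u_plus_c(u, matrix(0, 4, 5)),
               (u - min(u)) / (max(u) - min(u)))
  cc <- matrix(runif(20), 4, 5)
  naive <- (u - min(u)) / diff(range(u)) + (cc - min(cc)) / diff(range(cc))
  expect_equal(combined_u_plus_c(u, cc), naive)
  expect_error(combined_u_plus_c(u, matrix(0, 5, 4)), "shape")
})

test_that("field-of-view area matches the study geometries and scales correctly", {
  expect_equal(round(fov_area_mm2(field_geometry(0, 0, 1424, 1064), 0.279), 2), 0.12)
  expect_equal(round(fov_area_mm2(field_geometry(0, 0, 1024, 766), 0.38895), 2), 0.12)
  expect_equal(fov_area_mm2(field_geometry(0, 0, 1000, 1000), 1.0), 1.0)
  ## linear in pixel area, quadratic in isotropic mpp
  a1 <- fov_area_mm2(field_geometry(0, 0, 200, 100), 0.5)
  expect_equal(fov_area_mm2(field_geometry(0, 0, 400, 100), 0.5), 2 * a1)
  expect_equal(fov_area_mm2(field_geometry(0, 0, 200, 100), 1.0), 4 * a1)
})

test_that("field-set CSV round-trips", {
  df <- data.frame(slide_id = "s1", field_idx = 1:3, row = c(0, 10, 20),
                   col = c(5, 5, 5), width = 128, height = 128,
                   ki67_pct = c(10.5, NA, 3))
  f <- tempfile(fileext = ".csv")
  write_fieldsets(df, f)
  back <- read_fieldsets(f)
  expect_equal(back$row, df$row)
  expect_equal(back$ki67_pct, df$ki67_pct)
  unlink(f)
})
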