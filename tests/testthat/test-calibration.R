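test_that("ROI statistics follow the mean +/- SD (n), SE = SD/sqrt(n) convention", {
  set.seed(8)
  field <- array(rnorm(1000, 500, 80), dim = c(10, 10, 10))
  mask <- array(FALSE, dim = c(10, 10, 10))
  mask[3:8, 3:8, 2:9] <- TRUE
  st <- roi_stats(field, mask)
  v <- field[mask]
  expect_equal(st$n, sum(mask))
  expect_equal(st$mean, mean(v))
  expect_equal(st$sd, sqrt(mean((v - mean(v))^2)))  # population SD
  expect_identical(st$se, st$sd / sqrt(st$n))       # exact, not approximate
  # constant field -> sd = 0, se = 0
  st0 <- roi_stats(array(7, dim = c(3, 3, 1)), array(TRUE, dim = c(3, 3, 1)))
  expect_equal(st0$sd, 0)
  expect_equal(st0$se, 0)
  # invalid voxels are excluded; an all-invalid ROI is a distinct error
  m <- relaxation_map(field, field, mask, array("ok", dim(field)),
                      array(8L, dim(field)), kind = "R2*")
  expect_equal(roi_stats(m, mask)$n, sum(mask))
  expect_error(roi_stats(m, !mask), "no valid voxel")
})

test_that("calibration fit reproduces the reference table regression", {
  tab <- read_table1(table1_path())
  cal <- fit_calibration(tab$cfe_ug_ml, tab$mean_r2star)
  expect_equal(round(cal$slope, 2), 10.02)
  expect_equal(cal$intercept, 88.02273, tolerance = 1e-6)
  expect_equal(round(cal$r_squared, 2), 0.98)
  expect_equal(cal$n_points, 11L)
})

test_that("calibration fit handles exact lines and degenerate input", {
  cal <- fit_calibration(c(0, 1, 2, 5), 2 * c(0, 1, 2, 5) + 1)
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 1)
  expect_equal(cal$r_squared, 1)
  two <- fit_calibration(c(10, 20), c(150, 260))
  expect_equal(two$slope, 11)
  expect_equal(two$r_squared, 1)
  expect_error(fit_calibration(c(5, 5, 5), c(1, 2, 3)), "identical")
  expect_error(fit_calibration(numeric(0), numeric(0)), ">= 2")
})

test_that("r_squared matches an independent brute-force oracle", {
  set.seed(31)
  for (i in 1:5) {
    x <- sort(runif(8, 0, 100))
    y <- 5 * x + 40 + rnorm(8, sd = 30)
    cal <- fit_calibration(x, y)
    # oracle: squared Pearson correlation equals OLS R^2
    expect_equal(cal$r_squared, cor(x, y)^2, tolerance = 1e-12)
  }
})

test_that("calibration inversion round-trips and preserves sign information", {
  cal <- ref_calib()
  expect_equal(concentration_from_r2star(88.028, cal), 0,
               ignore_attr = TRUE)
  for (cc in c(9.6, 48, 96)) {
    expect_equal(
      concentration_from_r2star(true_r2star_from_concentration(cc, cal), cal),
      cc, ignore_attr = TRUE
    )
  }
  expect_equal(concentration_from_r2star(1074.0, cal), (1074 - 88.028) / 10.02,
               ignore_attr = TRUE)
  # baseline mode replaces the intercept
  expect_equal(concentration_from_r2star(130, cal, baseline_r2star = 100),
               (130 - 100) / 10.02, ignore_attr = TRUE)
  # negative outputs are retained and counted; clipping is opt-in
  vals <- c(70, 90, 110)
  conc <- concentration_from_r2star(vals, cal)
  expect_equal(attr(conc, "n_negative"), 1L)
  expect_lt(conc[1], 0)
  clipped <- concentration_from_r2star(vals, cal, clip_negative = TRUE)
  expect_equal(clipped[1], 0, ignore_attr = TRUE)
  expect_equal(attr(clipped, "n_negative"), 1L)
  expect_error(
    concentration_from_r2star(100, calibration_model(0, 50)), "slope"
  )
})

test_that("calibration models serialize to JSON and back", {
  cal <- fit_calibration(c(0, 10, 20, 40), c(90, 190, 290, 490))
  f <- tempfile(fileext = ".json")
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(back$slope, cal$slope)
  expect_equal(back$intercept, cal$intercept)
  expect_equal(back$r_squared, cal$r_squared)
  expect_equal(back$n_points, cal$n_points)
})

test_that("noiseless phantom chain recovers the generative calibration", {
  spec <- tiny_phantom_spec(noise_sigma = 0)
  img <- generate_phantom_image(spec, tiny_phantom_params(), seed = 1)
  m <- multi_echo_map(img)
  pts <- vial_calibration_points(m, attr(img, "vial_layout"),
                                 attr(img, "true_cfe"))
  cal <- fit_calibration(pts$cfe, pts$mean)
  expect_lt(abs(cal$slope - 10.02) / 10.02, 1e-3)
  expect_lt(abs(cal$intercept - 88.028) / 88.028, 1e-3)
  expect_equal(cal$r_squared, 1, tolerance = 1e-10)
})
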