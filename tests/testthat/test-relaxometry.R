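test_that("dual-echo closed form inverts forward-simulated decays", {
  params <- acquisition_preset("dual-echo-dynamic")
  # no decay between echoes -> rate 0
  img0 <- uniform_decay_image(0, s0 = 100, params)
  m0 <- dual_echo_r2star(img0)
  expect_true(all(m0$values == 0))
  # unit round trip at 50, 200 and 800 s^-1
  for (r in c(50, 200, 800)) {
    img <- uniform_decay_image(r, params = params)
    m <- dual_echo_r2star(img)
    expect_true(all(m$valid))
    expect_lt(max(abs(m$values - r) / r), 1e-10)
    expect_equal(m$s0[1, 1, 1], 1000, tolerance = 1e-10)
  }
  expect_equal(m0$kind, "R2*")
})

test_that("degenerate dual-echo voxels are flagged, not fatal", {
  params <- acquisition_preset("dual-echo-dynamic")
  img <- uniform_decay_image(100, params = params, dims = c(3, 3, 1))
  img$data[1, 1, 1, 2] <- 0
  m <- dual_echo_r2star(img)
  expect_false(m$valid[1, 1, 1])
  expect_equal(m$reason[1, 1, 1], "nonpositive_signal")
  expect_true(all(m$valid[-1]))
  expect_equal(sum(m$n_echoes_used == 2L), 8)
  expect_error(dual_echo_r2star(img, te1 = 7.2, te2 = 1.85), "te2 > te1")
  expect_error(dual_echo_r2star(img, te1 = 2, te2 = 9), "echo times of the image")
})

test_that("noise sigma is recovered from background and guarded when absent", {
  spec <- tiny_phantom_spec(noise_sigma = 50)
  img <- generate_phantom_image(spec, tiny_phantom_params(), seed = 2)
  bg <- attr(img, "vial_layout") == 0
  expect_gt(sum(bg), 1000)
  est <- estimate_noise_sigma(img, background_mask = bg)
  expect_equal(est$method, "background-roi")
  expect_lt(abs(est$sigma - 50) / 50, 0.05)
  # noiseless image -> sigma would be 0 -> error
  img0 <- generate_phantom_image(tiny_phantom_spec(noise_sigma = 0),
                                 tiny_phantom_params(), seed = 2)
  expect_error(estimate_noise_sigma(img0, background_mask = bg), "non-positive")
  expect_error(estimate_noise_sigma(img, background_mask = bg & FALSE), "empty")
  # provided sigma bypasses estimation
  prov <- estimate_noise_sigma(sigma = 12.5)
  expect_equal(prov$sigma, 12.5)
  expect_equal(prov$method, "provided")
})

test_that("SNR echo selection keeps the longest leading run", {
  expect_equal(select_echoes_by_snr(c(900, 500, 200, 90, 40), 50), 3L)
  expect_equal(select_echoes_by_snr(c(900, 500, 400), 50), 3L)
  expect_equal(select_echoes_by_snr(c(100, 900, 900), 50), 0L)
  # brute-force oracle over random decays
  brute <- function(m, sigma, thr) {
    k <- 0
    for (v in m) {
      if (v / sigma > thr) k <- k + 1 else break
    }
    k
  }
  set.seed(11)
  for (i in 1:50) {
    m <- abs(rnorm(8, mean = 300, sd = 200))
    expect_equal(select_echoes_by_snr(m, 50, 3), brute(m, 50, 3))
  }
  expect_error(select_echoes_by_snr(c(1, 2), sigma = 0), "sigma")
})

test_that("log-linear decay fit is exact on noiseless data", {
  te <- acquisition_preset("phantom-multiecho")$echo_times
  s <- 1000 * exp(-300 * te / 1000)
  f <- fit_exponential_decay(te, s)
  expect_equal(unname(f["rate"]), 300, tolerance = 1e-10)
  expect_equal(unname(f["amplitude"]), 1000, tolerance = 1e-10)
  # invariant to dropping trailing echoes: any n_keep >= 2 gives the rate
  for (k in 2:8) {
    expect_equal(unname(fit_exponential_decay(te, s, n_keep = k)["rate"]), 300,
                 tolerance = 1e-9)
  }
  # constant magnitudes -> rate 0
  expect_equal(unname(fit_exponential_decay(te, rep(500, 8))["rate"]), 0)
  # two echoes reproduce the dual-echo closed form
  s2 <- c(100, 100 * exp(-1.07))
  f2 <- fit_exponential_decay(c(1.85, 7.2), s2, n_keep = 2)
  expect_equal(unname(f2["rate"]), log(s2[1] / s2[2]) / ((7.2 - 1.85) / 1000),
               tolerance = 1e-12)
  # non-positive kept magnitude invalidates the voxel, not the call
  expect_true(all(is.na(fit_exponential_decay(te, c(100, -5, 50), n_keep = 3))))
  expect_error(fit_exponential_decay(te, s, n_keep = 1), "n_keep")
})

test_that("multi-echo map recovers generative rates on the noiseless phantom", {
  spec <- tiny_phantom_spec(noise_sigma = 0)
  img <- generate_phantom_image(spec, tiny_phantom_params(), seed = 1)
  m <- multi_echo_map(img)
  layout <- attr(img, "vial_layout")
  truth <- attr(img, "true_r2star")
  # voxelwise recovery to < 1e-10 relative error in every vial
  for (v in 1:11) {
    vals <- m$values[layout == v]
    expect_lt(max(abs(vals - truth[v]) / truth[v]), 1e-10)
    st <- roi_stats(m, layout == v)
    expect_lt(abs(st$mean - truth[v]) / truth[v], 1e-10)
  }
  # background voxels are invalid with a reason, not poisoned values
  expect_false(any(m$valid[layout == 0]))
  expect_true(all(m$reason[layout == 0] == "nonpositive_signal"))
  expect_equal(m$kind, "R2*")
})

test_that("spin-echo input produces an R2 map", {
  img <- uniform_decay_image(20, params = acquisition_preset("spin-echo-T2"))
  m <- multi_echo_map(img)
  expect_equal(m$kind, "R2")
  expect_equal(m$values[1, 1, 1], 20, tolerance = 1e-10)
})

test_that("log-linear fit agrees with a nonlinear least-squares oracle", {
  te <- acquisition_preset("phantom-multiecho")$echo_times
  # independent oracle: direct nonlinear least squares in the signal domain
  # (optim on the SSE; nls() itself rejects the zero-residual noiseless case)
  nls_rate <- function(te, s) {
    te_s <- te / 1000
    sse <- function(p) sum((s - p[1] * exp(-p[2] * te_s))^2)
    r0 <- max(10, log(max(s[1], 1e-9) / max(s[length(s)], 1e-9)) /
                (te_s[length(s)] - te_s[1]))
    fit <- stats::optim(c(max(s), r0), sse, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    fit$par[2]
  }
  # noiseless: < 0.1% disagreement
  for (r in c(100, 400, 700)) {
    s <- 1200 * exp(-r * te / 1000)
    expect_lt(abs(fit_exponential_decay(te, s)["rate"] - nls_rate(te, s)) / r,
              1e-3)
  }
  # sigma/S0 = 0.05: < 1% median disagreement over voxels, both estimators
  # seeing the same SNR-gated echoes (ungated noise-floor echoes are not a
  # regime either estimator is run on)
  set.seed(21)
  rel <- replicate(120, {
    r <- 250
    a <- 1000 * exp(-r * te / 1000)
    s <- sqrt((a + rnorm(8, sd = 50))^2 + rnorm(8, sd = 50)^2)
    k <- select_echoes_by_snr(s, sigma = 50, threshold = 3)
    if (k < 3) return(NA)
    ll <- unname(fit_exponential_decay(te, s, n_keep = k)["rate"])
    nl <- tryCatch(nls_rate(te[1:k], s[1:k]), error = function(e) NA)
    abs(ll - nl) / abs(nl)
  })
  expect_lt(median(rel, na.rm = TRUE), 0.01)
})

test_that("fit RMSE decreases monotonically with noise level", {
  params <- scale_acquisition_grid(acquisition_preset("phantom-multiecho"),
                                   c(24, 24, 1))
  layout <- one_region_layout(c(24, 24, 1))
  truth <- 300
  rmse <- sapply(c(100, 50, 25, 10), function(sig) {
    spec <- phantom_spec(
      vial_concentrations = (truth - 88.028) / 10.02 / 0.48 / 1000,
      vial_layout = layout, noise_sigma = sig
    )
    img <- generate_phantom_image(spec, params, seed = 13)
    m <- multi_echo_map(img, noise = estimate_noise_sigma(sigma = sig),
                        gate_regions = layout)
    vals <- m$values[layout == 1 & m$valid]
    expect_gt(length(vals), 350)
    sqrt(mean((vals - truth)^2))
  })
  expect_true(all(diff(rmse) < 0))
})

test_that("per-voxel SNR gating marks unfittable voxels with reasons", {
  params <- scale_acquisition_grid(acquisition_preset("phantom-multiecho"),
                                   c(8, 8, 1))
  te_s <- params$echo_times / 1000
  data <- array(0, dim = c(8, 8, 1, 8))
  for (e in 1:8) data[, , , e] <- 1000 * exp(-200 * te_s[e])
  # one voxel decays so fast that only its first echo clears 3 sigma
  for (e in 1:8) data[1, 1, 1, e] <- 1000 * exp(-1500 * te_s[e])
  img <- multi_echo_image(data, params)
  m <- multi_echo_map(img, noise = estimate_noise_sigma(sigma = 50))
  expect_false(m$valid[1, 1, 1])
  expect_equal(m$reason[1, 1, 1], "insufficient_echoes")
  expect_true(all(m$valid[-1]))
  expect_true(all(m$n_echoes_used[m$valid] >= 2))
  # whole-image failure is a distinct error
  dark <- multi_echo_image(array(1, dim = c(4, 4, 1, 8)), params = {
    p <- params; p$matrix_size <- c(4L, 4L); p
  })
  expect_error(multi_echo_map(dark, noise = estimate_noise_sigma(sigma = 50)),
               "whole-image")
})

test_that("slice resampling averages blocks and conserves region means", {
  swi <- acquisition_preset("swi-multiecho")
  se <- acquisition_preset("spin-echo-T2")
  dims <- c(6, 6, 48)
  params48 <- scale_acquisition_grid(swi, dims)
  ref24 <- scale_acquisition_grid(se, c(6, 6, 24))
  mk_map <- function(values) {
    relaxation_map(values, array(1, dims), array(TRUE, dims),
                   array("ok", dims), array(8L, dims),
                   kind = "R2*", params = params48)
  }
  # constant map is invariant
  const <- mk_map(array(123, dims))
  out <- resample_to_reference(const, ref24)
  expect_equal(dim(out$values), c(6, 6, 24))
  expect_true(all(out$values == 123))
  expect_equal(out$params$slice_thickness, 1)
  # alternating slices a, b -> uniform (a + b) / 2
  alt <- array(0, dims)
  alt[, , seq(1, 48, 2)] <- 10
  alt[, , seq(2, 48, 2)] <- 30
  out2 <- resample_to_reference(mk_map(alt), ref24)
  expect_true(all(out2$values == 20))
  # mean conservation over a fully valid region
  set.seed(3)
  rnd <- array(rnorm(prod(dims), 100, 5), dims)
  out3 <- resample_to_reference(mk_map(rnd), ref24)
  expect_equal(mean(out3$values), mean(rnd), tolerance = 1e-12)
  # invalid voxels are excluded, and all-invalid blocks stay invalid
  hole <- mk_map(rnd)
  hole$valid[1, 1, 1:2] <- FALSE
  hole$values[1, 1, 1:2] <- NA
  out4 <- resample_to_reference(hole, ref24)
  expect_false(out4$valid[1, 1, 1])
  expect_true(out4$valid[1, 1, 2])
  # non-integer thickness ratios are rejected
  bad_ref <- scale_acquisition_grid(se, c(6, 6, 24))
  bad_ref$slice_thickness <- 0.75
  expect_error(resample_to_reference(mk_map(rnd), bad_ref), "integer")
})
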