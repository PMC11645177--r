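test_that("noiseless time-course extraction reproduces the generative curves", {
  sp <- group_preset("group1", noise_sigma = 0)
  frames <- generate_dynamic_study(sp, seed = 1)
  truth <- attr(frames, "true_concentrations")
  cal <- ref_calib()
  for (roi in c("tumor", "normal")) {
    tc <- extract_timecourse(frames, sp$compartment_masks[[roi]], cal,
                             n_baseline = 9, roi_name = roi)
    expect_equal(tc$times, frame_times(sp))
    expect_lt(max(abs(tc$concentrations - truth[roi, ])), 1e-6)
  }
})

test_that("null-tracer study yields concentrations statistically at zero", {
  sp <- group_preset("group6", noise_sigma = 20)
  sp$concentration_curves <- list(tumor = NULL, normal = NULL, ventricle = NULL)
  frames <- generate_dynamic_study(sp, seed = 2)
  cal <- ref_calib()
  tc <- extract_timecourse(frames, sp$compartment_masks$tumor, cal, 9, "tumor")
  post <- post_injection(tc)
  for (i in seq_along(post$times)) {
    st <- tc$summaries[[which(tc$times == post$times[i])]]
    expect_lt(abs(post$concentrations[i]), 3 * st$se + 1e-9)
  }
  # the nine baseline concentrations average to ~0 by construction
  expect_lt(abs(mean(tc$concentrations[tc$times <= 0])), 1e-10)
})

test_that("scaling generative concentrations scales recovered ones", {
  cal <- ref_calib()
  get_tc <- function(k) {
    sp <- group_preset("group2", noise_sigma = 0, concentration_scale = k)
    frames <- generate_dynamic_study(sp, seed = 1)
    extract_timecourse(frames, sp$compartment_masks$tumor, cal, 9, "tumor")
  }
  tc1 <- get_tc(1)
  tc2 <- get_tc(2)
  post1 <- post_injection(tc1)$concentrations
  post2 <- post_injection(tc2)$concentrations
  expect_equal(post2, 2 * post1, tolerance = 1e-8)
})

test_that("extraction guards its preconditions", {
  sp <- group_preset("group1", noise_sigma = 0)
  frames <- generate_dynamic_study(sp, seed = 1)
  cal <- ref_calib()
  expect_error(extract_timecourse(frames[1:5], sp$compartment_masks$tumor,
                                  cal, 9), "more frames")
  empty <- array(FALSE, dim = dim(sp$compartment_masks$tumor))
  expect_error(extract_timecourse(frames, empty, cal, 9), "mask|valid")
  # mask over background voxels only: no valid baseline anywhere
  bg <- !(sp$compartment_masks$tumor | sp$compartment_masks$normal |
            sp$compartment_masks$ventricle)
  expect_error(extract_timecourse(frames, bg, cal, 9), "valid baseline")
})

test_that("peak time takes the post-injection maximum with early tie-break", {
  mk_tc <- function(conc) {
    times <- c(-1, 0, 30, 45, 60)
    roi_timecourse("t", times, conc,
                   replicate(5, list(mean = 0, sd = 0, n = 1, se = 0),
                             simplify = FALSE), n_baseline = 2)
  }
  expect_equal(peak_time(mk_tc(c(0, 0, 1, 2, 3))), 60)   # monotone -> last
  expect_equal(peak_time(mk_tc(c(0, 0, 1, 5, 2))), 45)
  expect_equal(peak_time(mk_tc(c(0, 0, 2, 2, 2))), 30)   # flat -> earliest
})

test_that("preferentiality windows follow the threshold rule", {
  times <- c(-1, 0, 30, 45, 60, 90, 120)
  mk_tc <- function(name, conc) {
    roi_timecourse(name, times, conc,
                   replicate(7, list(mean = 0, sd = 0, n = 1, se = 0),
                             simplify = FALSE), n_baseline = 2)
  }
  tumor <- mk_tc("tumor", c(0, 0, 4, 6, 4.5, 2.5, 1.2))
  # tumor == normal -> ratio 1 everywhere, empty window at threshold 1
  same <- preferentiality(tumor, mk_tc("normal", c(0, 0, 4, 6, 4.5, 2.5, 1.2)))
  expect_true(all(same$ratio_series == 1))
  expect_length(same$window, 0)
  # tumor = 2 x normal -> ratio 2, window covers all post-injection stamps
  dbl <- preferentiality(tumor, mk_tc("normal", c(0, 0, 2, 3, 2.25, 1.25, 0.6)))
  expect_true(all(dbl$ratio_series == 2))
  expect_equal(dbl$window, c(30, 45, 60, 90, 120))
  expect_equal(dbl$peak_time_tumor, 45)
  # non-positive normal concentration -> flagged, never preferential
  und <- preferentiality(tumor, mk_tc("normal", c(0, 0, 2, 0, 2.25, 1.25, 0.6)))
  expect_true(und$undefined[2])
  expect_true(is.na(und$ratio_series[2]))
  expect_false(45 %in% und$window)
  # mismatched time axes rejected
  other <- roi_timecourse("normal", times + 1, rep(0, 7),
                          replicate(7, list(mean = 0, sd = 0, n = 1, se = 0),
                                    simplify = FALSE), 2)
  expect_error(preferentiality(tumor, other), "time axes")
})

test_that("group-1 noiseless simulation gives the designed window and peak", {
  sp <- group_preset("group1", noise_sigma = 0)
  frames <- generate_dynamic_study(sp, seed = 1)
  cal <- ref_calib()
  tc_t <- extract_timecourse(frames, sp$compartment_masks$tumor, cal, 9, "tumor")
  tc_n <- extract_timecourse(frames, sp$compartment_masks$normal, cal, 9, "normal")
  pref <- preferentiality(tc_t, tc_n, threshold = 1)
  expect_equal(pref$window, c(30, 45, 60, 90))
  expect_equal(pref$peak_time_tumor, 45)
})

test_that("group reports are ordered, typed and reject duplicates", {
  times <- c(0, 30, 45)
  mk_tc <- function(name, conc) {
    roi_timecourse(name, times, conc,
                   replicate(3, list(mean = 0, sd = 0, n = 1, se = 0),
                             simplify = FALSE), n_baseline = 1)
  }
  p_pref <- preferentiality(mk_tc("t", c(0, 4, 6)), mk_tc("n", c(0, 2, 2)))
  p_null <- preferentiality(mk_tc("t", c(0, 2, 2)), mk_tc("n", c(0, 2, 2)))
  rep1 <- group_report(list(b_group = p_pref))
  expect_equal(nrow(rep1), 1)
  rep2 <- group_report(list(b_group = p_pref, a_null = p_null))
  expect_equal(rep2$group, c("a_null", "b_group"))  # stable label ordering
  # empty window renders as zero extent, not missing
  expect_equal(rep2$window_extent_min[rep2$group == "a_null"], 0)
  expect_equal(rep2$n_preferential[rep2$group == "a_null"], 0)
  expect_equal(rep2$window_start_min[rep2$group == "b_group"], 30)
  expect_error(group_report(list(a = p_pref, a = p_null)), "duplicate")
  expect_error(group_report(list()), "at least one")
  expect_error(group_report(list(p_pref)), "named")
})
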