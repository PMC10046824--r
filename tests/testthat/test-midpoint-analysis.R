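test_that("midpoint extrapolation recovers an ideal step exactly and is drift-invariant", {
  s <- schedule_ct()
  stair <- ideal_staircase(0.05 / s$t_open, s)
  est <- midpoint_cycles(stair, s)
  expect_equal(est$delta_T_mK, rep(0.05, s$n_cycles), tolerance = 1e-9)
  # adding any global linear trend changes nothing, to machine precision
  drifted <- stair
  drifted$temp_mK <- drifted$temp_mK + 0.001 * drifted$time_s - 7
  est_d <- midpoint_cycles(drifted, s)
  expect_equal(est_d$delta_T_mK, est$delta_T_mK, tolerance = 1e-12)
})

test_that("midpoint extrapolation tracks the slow-term staircase of the CT model", {
  s <- schedule_ct()
  wf <- forward_waveform(transient_params(0, 0.016, 1.4, 628), s,
                         component = "slow")
  est <- midpoint_cycles(wf, s)
  expect_equal(mean(est$delta_T_mK), 0.016 * s$t_open, tolerance = 5e-3)
})

test_that("window validation rejects under-sampled and out-of-range requests", {
  s <- schedule_ct()
  stair <- ideal_staircase(0.01, s)
  expect_error(extrapolate_midpoint(stair, s, cycle = 0), "1\\.\\.10")
  expect_error(extrapolate_midpoint(stair, s, cycle = 11), "1\\.\\.10")
  expect_error(extrapolate_midpoint(stair, s, 1, window_fraction = 0),
               "window_fraction")
  # a settle delay eating nearly the whole off-segment leaves < 3 samples
  expect_error(extrapolate_midpoint(stair, s, 1, settle_s = 7.6),
               "Fewer than 3 samples")
})

test_that("a noisy megavoltage run recovers the generating dose within 1 %", {
  s <- schedule_6mv()
  cp <- cp_ref()
  wf <- simulate_6mv_run(1.61, s, cp = cp, drift = small_drift(),
                         noise_sd_mK = 0.005, seed = 42)
  rd <- run_dose(midpoint_cycles(wf, s), cp)
  expect_equal(rd$n_cycles, 20L)
  expect_lt(abs(rd$dose_Gy / 1.61 - 1), 0.01)
  expect_gt(rd$sd_dose_Gy, 0)
})

test_that("run_dose averages cycles and flags the degenerate single-cycle case", {
  est <- tibble::tibble(delta_T_mK = rep(1.328, 20))
  rd <- run_dose(est, cp = 1212.3)
  expect_equal(rd$dose_Gy, 1.328 * 1212.3 / 1000)
  expect_equal(rd$sd_delta_T_mK, 0)
  one <- run_dose(tibble::tibble(delta_T_mK = 0.5), cp = 1208)
  expect_true(one$single_cycle)
  expect_identical(one$sd_dose_Gy, 0)
  mixed <- tibble::tibble(delta_T_mK = c(1.1, 1.3, 1.6))
  expect_equal(run_dose(mixed, 1208)$mean_delta_T_mK, (1.1 + 1.3 + 1.6) / 3)
  expect_error(run_dose(tibble::tibble(delta_T_mK = numeric(0)), 1208),
               "empty")
})

test_that("linearity regression reports slope, residuals and deviation from unity", {
  ref <- reference_doses("6mv")$ic_dose_Gy
  exact <- linear_calibration(tibble::tibble(
    reference_dose = ref, calorimeter_dose = ref))
  expect_equal(exact$slope, 1)
  expect_equal(exact$intercept, 0, tolerance = 1e-12)
  expect_equal(exact$residuals, rep(0, 5), tolerance = 1e-12)
  # synthetic-bias fixture: +1.6 % slope deviation
  biased <- linear_calibration(tibble::tibble(
    reference_dose = ref, calorimeter_dose = 1.016 * ref))
  expect_equal(biased$slope_dev_from_unity, 0.016, tolerance = 1e-9)
  td <- tidy(biased)
  expect_equal(td$estimate[td$term == "slope"], 1.016)
  expect_named(glance(biased),
               c("slope", "slope_se", "slope_dev_from_unity", "intercept",
                 "r.squared", "n"))
  expect_error(linear_calibration(tibble::tibble(
    reference_dose = rep(1, 3), calorimeter_dose = 1:3)), "distinct")
})

test_that("regression recovers a generating slope within 2 sd across seeds", {
  ref <- reference_doses("6mv")$ic_dose_Gy
  slopes <- withr::with_seed(2024, {
    vapply(seq_len(200), function(i) {
      cal <- 1.016 * ref + rnorm(5, sd = 0.01)
      linear_calibration(tibble::tibble(
        reference_dose = ref, calorimeter_dose = cal))$slope
    }, numeric(1))
  })
  se_mean <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 1.016), 2 * se_mean + 1e-4)
})

test_that("noiseless recovery is linear across the five reference doses", {
  s <- schedule_6mv()
  cp <- cp_ref()
  ref <- reference_doses("6mv")$ic_dose_Gy
  rec <- vapply(ref, function(d) {
    wf <- simulate_6mv_run(d, s, cp = cp, drift = small_drift(),
                           noise_sd_mK = 0, seed = 1)
    run_dose(midpoint_cycles(wf, s), cp)$dose_Gy
  }, numeric(1))
  cmp <- linear_calibration(tibble::tibble(
    reference_dose = ref, calorimeter_dose = rec))
  expect_lt(abs(cmp$slope_dev_from_unity), 0.01)
})
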