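test_that("noiseless fit recovers the generating parameters to optimizer tolerance", {
  runs <- simulate_ct_series(650, tbl1(), schedule_ct(),
                             drifts = small_drift(),
                             noise_sd_mK = 0, seed = 1)
  fit <- fit_transient(runs, schedule_ct())
  p <- fit$params
  expect_true(fit$converged)
  expect_lt(abs(p$k1 / 0.27 - 1), 1e-3)
  expect_lt(abs(p$k2 / 0.016 - 1), 1e-3)
  expect_lt(abs(p$tau1 / 1.4 - 1), 1e-3)
  expect_lt(abs(p$tau2 / 628 - 1), 1e-3)
  # residual at the noiseless optimum is zero to numerical tolerance
  expect_lt(fit$chi2_min, 1e-10)
  # drift nuisances are recovered too
  expect_equal(fit$per_run_drifts$slope, small_drift()$slope,
               tolerance = 1e-4)
  # transient-to-step weight ratio
  expect_equal(round(glance(fit)$k1_over_k2), 17)
})

test_that("recovered weights scale linearly with a global amplitude rescale", {
  runs <- simulate_ct_series(100, tbl1(), schedule_ct(),
                             noise_sd_mK = 0.002, seed = 9)
  fit1 <- fit_transient(runs, schedule_ct(), init = tbl1())
  runs2 <- runs
  runs2$waveform[[1]]$temp_mK <- 3 * runs2$waveform[[1]]$temp_mK
  fit2 <- fit_transient(runs2, schedule_ct(), init = tbl1())
  expect_equal(fit2$params$k1, 3 * fit1$params$k1, tolerance = 1e-6)
  expect_equal(fit2$params$k2, 3 * fit1$params$k2, tolerance = 1e-6)
})

test_that("a multi-run fit shares the response across tube-current settings", {
  runs <- simulate_ct_series(c(150, 400, 650), tbl1(), schedule_ct(),
                             noise_sd_mK = 0.002, seed = 4)
  fit <- fit_transient(runs, schedule_ct(), init = tbl1())
  expect_equal(nrow(fit$per_run_drifts), 3)
  expect_lt(abs(fit$params$tau1 / 1.4 - 1), 0.05)
  expect_lt(abs(fit$params$k1 / 0.27 - 1), 0.05)
  aug <- augment(fit)
  expect_equal(nrow(aug), fit$n_points)
  expect_lt(max(abs(aug$residual)), 0.01) # ~5 sigma of the noise
})

test_that("parameter recovery holds in the median over many noisy fixtures", {
  truth <- c(k1 = 0.27, k2 = 0.016, tau1 = 1.4, tau2 = 628)
  rec <- vapply(seq_len(50), function(i) {
    runs <- simulate_ct_series(100, tbl1(), schedule_ct(),
                               noise_sd_mK = 0.002, seed = 5000 + i)
    f <- fit_transient(runs, schedule_ct(), init = tbl1())
    c(f$params$k1, f$params$k2, f$params$tau1, f$params$tau2)
  }, numeric(4))
  med <- apply(rec, 1, median)
  expect_true(all(abs(med / truth - 1) < 0.05))
})

test_that("chi-square doubling interval matches closed forms", {
  # quadratic: chi2 = 1 + (th - 2)^2 doubles at th = 2 +/- 1
  q <- chi2_doubling_interval(function(th) 1 + (th - 2)^2, best = 2,
                              lower = -10, upper = 10)
  expect_equal(q$lower_dev, -1, tolerance = 1e-6)
  expect_equal(q$upper_dev, 1, tolerance = 1e-6)
  # asymmetric piecewise branches
  pw <- chi2_doubling_interval(
    function(th) if (th > 2) 1 + (th - 2)^2 else 1 + 4 * (th - 2)^2,
    best = 2, lower = -10, upper = 10)
  expect_equal(pw$lower_dev, -0.5, tolerance = 1e-6)
  expect_equal(pw$upper_dev, 1, tolerance = 1e-6)
  # doubling never reached inside the scan bounds -> open side
  flat <- chi2_doubling_interval(function(th) 1 + 0.001 * (th - 2)^2,
                                 best = 2, lower = 1.9, upper = 2.1)
  expect_true(is.na(flat$lower_dev) && is.na(flat$upper_dev))
})

test_that("profile intervals behave sensibly on a noisy fixture", {
  runs <- simulate_ct_series(650, tbl1(), schedule_ct(),
                             drifts = small_drift(),
                             noise_sd_mK = 0.002, seed = 21)
  fit <- fit_transient(runs, schedule_ct(), init = tbl1())
  iv1 <- param_uncertainty(fit, "tau1")
  expect_lt(iv1$lower_dev, 0)
  expect_gt(iv1$upper_dev, 0)
  # the true value lies inside the doubling interval
  expect_gt(1.4, iv1$best_value + iv1$lower_dev)
  expect_lt(1.4, iv1$best_value + iv1$upper_dev)
  # slow time constant: same order of magnitude as the published
  # (-50, +86) s band
  iv2 <- param_uncertainty(fit, "tau2")
  expect_gt(abs(iv2$lower_dev), 50 / 10)
  expect_lt(abs(iv2$lower_dev), 50 * 10)
  expect_gt(iv2$upper_dev, 86 / 10)
  expect_lt(iv2$upper_dev, 86 * 10)
  # the strict slice (nuisances frozen) is never wider than the profile
  strict <- param_uncertainty(fit, "tau1", profile = "none")
  expect_lte(abs(strict$lower_dev), abs(iv1$lower_dev) + 1e-9)
  expect_lte(strict$upper_dev, iv1$upper_dev + 1e-9)
})

test_that("the core staircase component converts to dose per 100 mA-s", {
  runs <- simulate_ct_series(650, tbl1(), schedule_ct(),
                             noise_sd_mK = 0, seed = 1)
  fit <- fit_transient(runs, schedule_ct())
  ps <- ps_component_dose(fit, cp = 1208, ic_dose_mGy = 2.46)
  # per-cycle rise of the isolated slow term ~ k2 * t_open
  expect_equal(ps$mean_delta_T_mK, 0.016 * 2, tolerance = 5e-3)
  # close to the published ~36 mGy per cycle per 100 mA-s estimate
  expect_equal(ps$dose_mGy_per_100mAs, 36, tolerance = 0.1)
  expect_gt(ps$dose_ratio, 10)
  expect_lt(ps$dose_ratio, 20)
  # a vanished slow term gives zero dose
  runs0 <- simulate_ct_series(100, transient_params(0.27, 0, 1.4, 628),
                              schedule_ct(), noise_sd_mK = 0, seed = 1)
  fit0 <- fit_transient(runs0, schedule_ct(), init = tbl1())
  ps0 <- ps_component_dose(fit0, cp = 1208)
  expect_lt(abs(ps0$dose_mGy_per_100mAs), 1e-6)
})
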