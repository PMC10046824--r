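test_that("timing function implements the half-open pulse-train convention", {
  s <- irradiation_schedule(2, 10, 10, t_start = 8, dt = 0.25)
  expect_identical(timing_function(8.5, s), 1)   # inside first pulse
  expect_identical(timing_function(8, s), 1)     # on at the leading edge
  expect_identical(timing_function(10, s), 0)    # off at the trailing edge
  expect_identical(timing_function(13, s), 0)    # mid off-segment
  expect_identical(timing_function(5, s), 0)     # before the train
  expect_identical(timing_function(8 + 10 * 10, s), 0) # after the train
  # Riemann mean over one period approximates the duty cycle
  t <- seq(8, 18 - s$dt, by = s$dt)
  expect_equal(mean(timing_function(t, s)), s$t_open / s$period,
               tolerance = s$dt / s$period)
  expect_error(irradiation_schedule(10, 10, 5), "t_open")
  expect_error(irradiation_schedule(2, 10, 0), "positive integer")
})

test_that("analytic convolution matches the closed-form single-pulse response", {
  s <- irradiation_schedule(2, 50, 1, t_start = 0, dt = 0.001)
  wf <- forward_waveform(transient_params(1, 0, 1.4, 100), s,
                         component = "fast")
  # at end of the pulse: k tau (1 - exp(-t_open / tau))
  v <- wf$temp_mK[which.min(abs(wf$time_s - 2))]
  expect_equal(v, 1 * 1.4 * (1 - exp(-2 / 1.4)), tolerance = 1e-3)
  # decaying tail
  v10 <- wf$temp_mK[which.min(abs(wf$time_s - 12))]
  expect_equal(v10, 1.4 * expm1(2 / 1.4) * exp(-12 / 1.4), tolerance = 1e-3)
})

test_that("the slow term approaches a pure staircase for very large tau2", {
  s <- schedule_ct()
  wf <- forward_waveform(transient_params(0, 1, 1, 1e9), s,
                         component = "slow")
  total <- wf$temp_mK[nrow(wf)]
  expect_equal(total, 1 * s$t_open * s$n_cycles, tolerance = 1e-6)
  # per-cycle increase of the isolated slow term for tau2 >> period
  s2 <- schedule_ct()
  wf2 <- forward_waveform(transient_params(0.27, 0.016, 1.4, 1e5), s2,
                          component = "slow")
  at <- function(x, tt) x$temp_mK[which.min(abs(x$time_s - tt))]
  step <- at(wf2, 8 + 6 * 10 - 0.25) - at(wf2, 8 + 5 * 10 - 0.25)
  expect_equal(step, 0.016 * s2$t_open, tolerance = 5e-3)
})

test_that("forward model is linear in term weights and drift", {
  s <- schedule_ct()
  p1 <- transient_params(0.27, 0.016, 1.4, 628)
  p2 <- transient_params(2 * 0.27, 2 * 0.016, 1.4, 628)
  w1 <- forward_waveform(p1, s)
  w2 <- forward_waveform(p2, s)
  expect_equal(w2$temp_mK, 2 * w1$temp_mK)
  d <- drift_params(3e-4, -0.2)
  wd <- forward_waveform(p1, s, drift = d)
  expect_equal(wd$temp_mK, w1$temp_mK + 3e-4 * w1$time_s - 0.2)
  # with zero weights the output is exactly the drift line
  w0 <- forward_waveform(transient_params(0, 0, 1.4, 628), s, drift = d)
  expect_identical(w0$temp_mK, 3e-4 * w0$time_s - 0.2)
})

test_that("discrete rectangle-rule mode underestimates and converges as dt -> 0", {
  p <- tbl1()
  s <- schedule_ct()
  wa <- forward_waveform(p, s)
  wd <- forward_waveform(p, s, mode = "discrete")
  i <- wa$temp_mK > 0.05
  expect_true(all(wd$temp_mK[i] <= wa$temp_mK[i] * (1 + 1e-9)))
  # compensation rescales the discrete output multiplicatively
  wc <- forward_waveform(p, s, mode = "discrete", compensation = 1 / 0.82)
  expect_equal(wc$temp_mK, wd$temp_mK / 0.82)
  # convergence on a fine grid
  sf <- irradiation_schedule(2, 10, 10, t_start = 8, dt = 0.001)
  wa2 <- forward_waveform(p, sf)
  wd2 <- forward_waveform(p, sf, mode = "discrete")
  j <- wa2$temp_mK > 0.05
  expect_lt(max(abs(wd2$temp_mK[j] - wa2$temp_mK[j]) / wa2$temp_mK[j]), 1e-3)
})

test_that("unresolved pulses are rejected and CSV round-trips exactly", {
  s_bad <- irradiation_schedule(2, 10, 3, dt = 2)
  expect_error(forward_waveform(tbl1(), s_bad), "unresolved")
  wf <- forward_waveform(tbl1(), schedule_ct(), drift = small_drift())
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(wf, path)
  expect_identical(readLines(path, n = 1), "time_s,temp_mK")
  back <- read_waveform_csv(path)
  expect_equal(back$temp_mK, wf$temp_mK, tolerance = 1e-12)
})
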