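sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

# Trim a (detrended) waveform to the integer-cycle window
# [t_start, t_start + n_cycles * period).
trim_to_cycles <- function(waveform, schedule) {
  t_end <- schedule_end(schedule)
  idx <- waveform$time_s >= schedule$t_start - 1e-9 &
    waveform$time_s < t_end - 1e-9
  n_per_period <- schedule$period / schedule$dt
  if (abs(n_per_period - round(n_per_period)) > 1e-6) {
    abort("`period` must be an integer multiple of `dt` for spectral analysis.")
  }
  if (sum(idx) < n_per_period) {
    abort("Waveform is shorter than one period.")
  }
  n_keep <- schedule$n_cycles * round(n_per_period)
  keep <- which(idx)[seq_len(min(n_keep, sum(idx)))]
  waveform[keep, ]
}

#' Amplitude of a duty-cycle harmonic of a temperature record
#'
#' Trims the record to the integer number of cycles covered by the
#' schedule, removes a linear trend fitted within that window, and returns
#' the one-sided discrete-Fourier amplitude `2 |X_k| / N` at harmonic `n`
#' of the cycle frequency `1 / period`. The bin is located from the
#' schedule (harmonic `n` of an integer-cycle record falls exactly in bin
#' `n * n_cycles`), not by peak search, so drift leakage cannot mislocate
#' it. The trend is fitted inside the analysis window (not over any
#' lead-in or trailing baseline) because a trend mismatch of slope `m`
#' leaks an amplitude of about `m * T / (pi k)` into bin `k`; fitting
#' within the window keeps that residual negligible.
#'
#' @param waveform A waveform tibble (`time_s`, `temp_mK`).
#' @param schedule An [irradiation_schedule()].
#' @param n Harmonic number (default 1, the fundamental).
#' @param detrend Remove a full-record linear trend first (default TRUE).
#' @return Amplitude in mK.
#' @examples
#' wf <- simulate_ct_series(100, noise_sd_mK = 0, seed = 1)$waveform[[1]]
#' fundamental_amplitude(wf, schedule_ct())
#' @export
fundamental_amplitude <- function(waveform, schedule, n = 1,
                                  detrend = TRUE) {
  waveform <- as_waveform(waveform)
  stopifnot(inherits(schedule, "irradiation_schedule"))
  if (n < 1 || n != round(n)) abort("`n` must be a positive integer.")
  wf <- trim_to_cycles(waveform, schedule)
  if (detrend) {
    trend <- lm(temp_mK ~ time_s, data = wf)
    wf$temp_mK <- wf$temp_mK - unname(predict(trend))
  }
  N <- nrow(wf)
  k <- n * schedule$n_cycles # 0-based bin of harmonic n
  if (k >= N / 2) abort("Harmonic `n` is beyond the Nyquist frequency.")
  X <- fft(wf$temp_mK)
  2 * Mod(X[k + 1L]) / N
}

#' Heating rate from a duty-cycle harmonic amplitude
#'
#' For an ideal staircase record — temperature rising at rate `A` mK/s
#' while the beam is on, holding while it is off — the one-sided amplitude
#' of harmonic `n` is
#' \deqn{\mathrm{amp} = A \frac{t_{open}}{n\pi}\,
#'   \mathrm{sinc}\!\left(\frac{n\pi\, t_{open}}{period}\right),}
#' with `sinc(x) = sin(x)/x`. This function inverts that relation to
#' recover `A` (mK/s); the per-cycle temperature rise is then
#' `A * t_open`.
#'
#' @param amplitude Harmonic amplitude, mK (non-negative).
#' @param schedule An [irradiation_schedule()].
#' @param n Harmonic number.
#' @return Heating rate `A` in mK/s.
#' @examples
#' rate_from_amplitude(0.1, schedule_ct()) # mK/s
#' @export
rate_from_amplitude <- function(amplitude, schedule, n = 1) {
  stopifnot(inherits(schedule, "irradiation_schedule"))
  if (any(amplitude < 0)) abort("`amplitude` must be non-negative.")
  x <- n * pi * schedule$t_open / schedule$period
  s <- sinc(x)
  if (abs(s) < 1e-12) {
    abort(sprintf(
      "Harmonic n = %d falls on a sinc zero for duty cycle %g; no inversion.",
      n, schedule$t_open / schedule$period))
  }
  amplitude * n * pi / (schedule$t_open * s)
}

#' Spectral per-cycle temperature-rise estimate of one run
#'
#' Combines [fundamental_amplitude()] and [rate_from_amplitude()] into the
#' model-independent per-cycle rise estimate of a record.
#'
#' @inheritParams fundamental_amplitude
#' @return One-row tibble: `fundamental_amplitude_mK`,
#'   `heating_rate_mK_s`, `per_cycle_rise_mK`, `n_harmonic`.
#' @export
spectral_estimate <- function(waveform, schedule, n = 1, detrend = TRUE) {
  amp <- fundamental_amplitude(waveform, schedule, n = n, detrend = detrend)
  A <- rate_from_amplitude(amp, schedule, n = n)
  tibble(
    fundamental_amplitude_mK = amp,
    heating_rate_mK_s = A,
    per_cycle_rise_mK = A * schedule$t_open,
    n_harmonic = as.integer(n)
  )
}

#' Dose response of spectral rise estimates against reference doses
#'
#' Ordinary least-squares regression of per-cycle temperature rise (mK)
#' on reference ionization-chamber dose (mGy), with the excess-heat factor
#' of the fitted slope (its ratio to the ideal core-only slope
#' `1 / cp` mK/mGy).
#'
#' @param data A data frame with columns `per_cycle_rise_mK` and
#'   `ic_dose_mGy` (at least two distinct doses).
#' @param cp Specific heat capacity, J/(kg K).
#' @return One-row tibble: `slope_mK_per_mGy`, `slope_se`, `intercept`,
#'   `r_squared`, `excess_factor`, `excess_factor_rounded`, `n`.
#' @examples
#' runs <- simulate_ct_series(c(150, 400, 650), seed = 3)
#' est <- dplyr::bind_cols(
#'   runs["setting_mAs"],
#'   purrr::map_dfr(runs$waveform, spectral_estimate, schedule = schedule_ct())
#' )
#' est$ic_dose_mGy <- 2.46 * est$setting_mAs / 100
#' dose_response(est, cp = 1208)
#' @export
dose_response <- function(data, cp = 1208) {
  check_cp(cp)
  if (!is.data.frame(data) ||
      !all(c("per_cycle_rise_mK", "ic_dose_mGy") %in% names(data))) {
    abort("Need columns `per_cycle_rise_mK` and `ic_dose_mGy`.")
  }
  if (nrow(data) < 2 || length(unique(data$ic_dose_mGy)) < 2) {
    abort("Need at least 2 distinct reference doses.")
  }
  fit <- lm(per_cycle_rise_mK ~ ic_dose_mGy, data = data)
  sm <- suppressWarnings(summary(fit)) # noiseless fixtures fit perfectly
  slope <- unname(coef(fit)[2])
  tibble(
    slope_mK_per_mGy = slope,
    slope_se = unname(sm$coefficients[2, 2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    excess_factor = excess_heat_factor(slope, cp),
    excess_factor_rounded = excess_heat_factor(slope, cp, rounded = TRUE),
    n = nrow(data)
  )
}
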