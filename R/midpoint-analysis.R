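#' Per-cycle temperature rise by midpoint extrapolation
#'
#' The standard calorimetric estimate of the temperature rise of one
#' irradiation cycle: a straight line is fitted to the beam-off segment
#' preceding the pulse and another to the beam-off segment following it,
#' both lines are extrapolated to the temporal midpoint of the beam-on
#' interval, and the rise is the difference of the two extrapolations.
#' Because any global linear drift contributes identically to both lines
#' at the same instant, the estimate is exactly invariant to linear drift.
#'
#' The pre-fit uses the trailing `window_fraction` of the preceding
#' off-segment; the post-fit uses the leading `window_fraction` of the
#' following off-segment after an optional settle delay `settle_s`
#' (useful when a fast sensor transient must decay before the baseline is
#' trustworthy, as in the CT regime — a delay of about five fast time
#' constants is then appropriate).
#'
#' @param waveform A waveform tibble (`time_s`, `temp_mK`).
#' @param schedule An [irradiation_schedule()]; cycle boundaries come from
#'   the declared schedule, not from edge detection.
#' @param cycle Cycle index, 1-based, in `1..n_cycles`.
#' @param window_fraction Fraction of each off-segment used for the fits,
#'   in (0, 1].
#' @param settle_s Settle delay before the post-irradiation window, s.
#' @return One-row tibble: `cycle`, `delta_T_mK`, `t_mid_s`, and the
#'   fitted `pre_slope`, `pre_offset`, `post_slope`, `post_offset`
#'   (mK/s and mK).
#' @seealso [midpoint_cycles()] for all cycles at once.
#' @export
extrapolate_midpoint <- function(waveform, schedule, cycle,
                                 window_fraction = 0.5, settle_s = 0) {
  waveform <- as_waveform(waveform)
  stopifnot(inherits(schedule, "irradiation_schedule"))
  if (cycle < 1 || cycle > schedule$n_cycles || cycle != round(cycle)) {
    abort(sprintf("`cycle` must be an integer in 1..%d.", schedule$n_cycles))
  }
  if (window_fraction <= 0 || window_fraction > 1) {
    abort("`window_fraction` must be in (0, 1].")
  }
  off_len <- schedule$period - schedule$t_open
  if (settle_s < 0 || settle_s >= off_len) {
    abort("`settle_s` must be in [0, off-segment length).")
  }
  on_start <- schedule$t_start + (cycle - 1) * schedule$period
  t_mid <- on_start + schedule$t_open / 2

  pre_win <- c(on_start - window_fraction * off_len, on_start)
  post_start <- on_start + schedule$t_open + settle_s
  post_win <- c(post_start,
                post_start + window_fraction * (off_len - settle_s))

  fit_window <- function(win, label) {
    idx <- waveform$time_s >= win[1] & waveform$time_s < win[2]
    if (sum(idx) < 3) {
      abort(sprintf(
        "Fewer than 3 samples in the %s window [%g, %g) s.",
        label, win[1], win[2]))
    }
    fit <- lm(temp_mK ~ time_s, data = waveform[idx, ])
    coef(fit)
  }
  pre <- fit_window(pre_win, "pre-irradiation")
  post <- fit_window(post_win, "post-irradiation")

  tibble(
    cycle = as.integer(cycle),
    delta_T_mK = unname((post[1] + post[2] * t_mid) -
                          (pre[1] + pre[2] * t_mid)),
    t_mid_s = t_mid,
    pre_slope = unname(pre[2]), pre_offset = unname(pre[1]),
    post_slope = unname(post[2]), post_offset = unname(post[1])
  )
}

#' @param cycles Which cycles to analyse (default: all in the schedule).
#' @param ... Passed on to [extrapolate_midpoint()].
#' @rdname extrapolate_midpoint
#' @return `midpoint_cycles()`: one row per cycle.
#' @export
midpoint_cycles <- function(waveform, schedule,
                            cycles = seq_len(schedule$n_cycles), ...) {
  purrr::map_dfr(cycles, function(m) {
    extrapolate_midpoint(waveform, schedule, m, ...)
  })
}

#' Run-level dose from per-cycle estimates
#'
#' Averages the per-cycle temperature rises of a run and converts the mean
#' to absorbed dose with the supplied heat capacity. The spread is the
#' standard deviation over cycles (reported as 0, with `single_cycle =
#' TRUE`, when only one cycle is available).
#'
#' @param estimates A tibble with a `delta_T_mK` column, e.g. from
#'   [midpoint_cycles()].
#' @param cp Specific heat capacity, J/(kg K).
#' @return One-row tibble: `mean_delta_T_mK`, `sd_delta_T_mK`, `n_cycles`,
#'   `dose_Gy`, `sd_dose_Gy`, `cp_used`, `single_cycle`.
#' @export
run_dose <- function(estimates, cp) {
  check_cp(cp)
  if (!is.data.frame(estimates) || !"delta_T_mK" %in% names(estimates)) {
    abort("`estimates` must be a data frame with a `delta_T_mK` column.")
  }
  d <- estimates$delta_T_mK
  if (length(d) == 0) abort("`estimates` is empty.")
  single <- length(d) == 1L
  sd_mK <- if (single) 0 else sd(d)
  tibble(
    mean_delta_T_mK = mean(d),
    sd_delta_T_mK = sd_mK,
    n_cycles = length(d),
    dose_Gy = dose_from_delta_T(mean(d), cp) / 1000, # mK * cp = mGy
    sd_dose_Gy = dose_from_delta_T(sd_mK, cp) / 1000,
    cp_used = cp,
    single_cycle = single
  )
}

#' Linearity regression of calorimeter dose against reference dose
#'
#' Ordinary least-squares fit of `calorimeter_dose ~ reference_dose`
#' (intercept included). The headline diagnostic is the fractional
#' deviation of the slope from unity.
#'
#' @param comparison A data frame with columns `calorimeter_dose` and
#'   `reference_dose` (same units, typically Gy or mGy).
#' @return An object of class `dose_comparison`; see [tidy()] and
#'   [glance()] methods, and `$slope`, `$intercept`, `$slope_se`,
#'   `$slope_dev_from_unity`, `$residuals`.
#' @examples
#' cmp <- linear_calibration(tibble::tibble(
#'   reference_dose = c(0.536, 1.07, 1.61, 2.15, 2.69),
#'   calorimeter_dose = 1.016 * c(0.536, 1.07, 1.61, 2.15, 2.69)
#' ))
#' cmp$slope_dev_from_unity
#' @export
linear_calibration <- function(comparison) {
  if (!is.data.frame(comparison) ||
      !all(c("calorimeter_dose", "reference_dose") %in% names(comparison))) {
    abort("Need columns `calorimeter_dose` and `reference_dose`.")
  }
  if (nrow(comparison) < 2 ||
      length(unique(comparison$reference_dose)) < 2) {
    abort("Need at least 2 distinct reference doses.")
  }
  fit <- lm(calorimeter_dose ~ reference_dose, data = comparison)
  # summary.lm warns on noiseless (numerically perfect) fixtures
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  structure(
    list(
      fit = fit,
      data = as_tibble(comparison),
      slope = slope,
      intercept = unname(coef(fit)[1]),
      slope_se = unname(sm$coefficients[2, 2]),
      slope_dev_from_unity = slope - 1,
      residuals = unname(stats::residuals(fit)),
      r_squared = sm$r.squared
    ),
    class = "dose_comparison"
  )
}

#' @export
print.dose_comparison <- function(x, ...) {
  cat("<dose_comparison>\n")
  cat(sprintf("  n = %d paired doses\n", nrow(x$data)))
  cat(sprintf("  slope = %.4f +/- %.4f (%+.2f%% from unity), intercept = %.4g\n",
              x$slope, x$slope_se, 100 * x$slope_dev_from_unity, x$intercept))
  cat(sprintf("  R^2 = %.5f\n", x$r_squared))
  invisible(x)
}

#' @rdname linear_calibration
#' @param x A `dose_comparison`.
#' @param ... Unused.
#' @export
tidy.dose_comparison <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = unname(sm[, 1]),
    std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4])
  )
}

#' @rdname linear_calibration
#' @export
glance.dose_comparison <- function(x, ...) {
  tibble(
    slope = x$slope,
    slope_se = x$slope_se,
    slope_dev_from_unity = x$slope_dev_from_unity,
    intercept = x$intercept,
    r.squared = x$r_squared,
    n = nrow(x$data)
  )
}
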