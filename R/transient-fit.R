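# Unit-amplitude convolution basis: response of one exponential term with
# weight 1 and time constant tau to the full pulse train, evaluated at the
# sample times t. "discrete" replicates the rectangle-rule scheme of
# forward_waveform() and requires t to lie on the dt grid anchored at 0.
conv_basis <- function(t, tau, schedule, mode = "analytic") {
  if (mode == "analytic") {
    u <- numeric(length(t))
    for (a in pulse_starts(schedule)) {
      u <- u + exp_boxcar(t, 1, tau, a, schedule$t_open)
    }
    return(u)
  }
  dt <- schedule$dt
  idx <- round(t / dt) + 1L
  if (max(abs(t - (idx - 1L) * dt)) > 1e-6 * dt) {
    abort("\"discrete\" fitting needs samples on the dt grid anchored at 0.")
  }
  grid <- (seq_len(max(idx)) - 1L) * dt
  f <- timing_function(grid, schedule)
  h <- exp(-(seq_along(grid) * dt) / tau)
  conv <- stats::convolve(f, rev(h), type = "open")
  u <- dt * c(0, conv[seq_len(length(grid) - 1L)])
  u[idx]
}

# Coerce the accepted run formats to a tibble(setting_mAs, waveform).
as_run_set <- function(runs) {
  if (is.data.frame(runs) && "time_s" %in% names(runs)) {
    runs <- tibble(setting_mAs = 100, waveform = list(as_waveform(runs)))
  }
  if (!is.data.frame(runs) ||
      !all(c("setting_mAs", "waveform") %in% names(runs))) {
    abort(paste("`runs` must be a waveform or a tibble with columns",
                "`setting_mAs` and `waveform`."))
  }
  runs$waveform <- purrr::map(runs$waveform, as_waveform)
  runs
}

# Residual sum of squares at fixed time constants, with the amplitude and
# drift parameters (all linear) solved exactly by least squares
# (variable projection). Returns the rss and the linear coefficients.
vp_solve <- function(runs, schedule, tau1, tau2, mode) {
  R <- nrow(runs)
  n_r <- vapply(runs$waveform, nrow, integer(1))
  N <- sum(n_r)
  X <- matrix(0, N, 2L + 2L * R)
  y <- numeric(N)
  pos <- 0L
  for (r in seq_len(R)) {
    wf <- runs$waveform[[r]]
    rows <- pos + seq_len(n_r[r])
    s <- runs$setting_mAs[r] / 100
    X[rows, 1L] <- s * conv_basis(wf$time_s, tau1, schedule, mode)
    X[rows, 2L] <- s * conv_basis(wf$time_s, tau2, schedule, mode)
    X[rows, 2L + 2L * r - 1L] <- wf$time_s
    X[rows, 2L + 2L * r] <- 1
    y[rows] <- wf$temp_mK
    pos <- pos + n_r[r]
  }
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(
    rss = sum(fit$residuals^2),
    k1 = unname(cf[1L]), k2 = unname(cf[2L]),
    drifts = tibble(
      run = seq_len(R),
      setting_mAs = runs$setting_mAs,
      slope = unname(cf[2L + 2L * seq_len(R) - 1L]),
      offset = unname(cf[2L + 2L * seq_len(R)])
    ),
    fitted = fit$fitted.values,
    n_points = N
  )
}

#' Fit the two-exponential convolution model to CT waveforms
#'
#' Minimises the unweighted sum of squared residuals between measured
#' waveforms and the forward model over the shared response parameters
#' (k1, k2, tau1, tau2) and per-run linear-drift nuisance parameters.
#' Amplitudes are understood per 100 mA·s: each run's model is scaled by
#' `setting_mAs / 100`, so a series at several tube currents constrains a
#' single response shape (the response is dose-rate independent).
#'
#' Because the model is linear in (k1, k2) and in every drift parameter,
#' those are profiled out exactly by least squares at each candidate
#' (tau1, tau2); the two time constants — which differ by orders of
#' magnitude — are found by a coarse logarithmic grid search refined with
#' a derivative-free simplex. The procedure is deterministic for a given
#' input.
#'
#' @param runs A tibble with columns `setting_mAs` and `waveform`
#'   (list-column of waveform tibbles), e.g. from [simulate_ct_series()];
#'   a single waveform tibble is treated as one run at 100 mA·s.
#' @param schedule The shared [irradiation_schedule()].
#' @param init Optional [transient_params()] used to centre the time
#'   constant search grid.
#' @param mode `"analytic"` (exact convolution, default) or `"discrete"`
#'   (rectangle rule on the sample grid).
#' @param tau_bounds Length-2 positive limits for both time constants;
#'   a fit converging onto a bound is an error.
#' @return An object of class `transient_fit` with elements `params`
#'   ([transient_params()]), `per_run_drifts`, `chi2_min`, `n_points`,
#'   `mode`, `converged`, plus the inputs. Supports [tidy()], [glance()],
#'   [augment.transient_fit()] and [autoplot()].
#' @examples
#' runs <- simulate_ct_series(c(650), noise_sd_mK = 0, seed = 1)
#' fit <- fit_transient(runs, schedule_ct())
#' tidy(fit)
#' @export
fit_transient <- function(runs, schedule, init = NULL,
                          mode = c("analytic", "discrete"),
                          tau_bounds = c(1e-3, 1e6)) {
  mode <- match.arg(mode)
  runs <- as_run_set(runs)
  stopifnot(inherits(schedule, "irradiation_schedule"))
  if (!is.null(init)) stopifnot(inherits(init, "transient_params"))

  obj <- function(log_tau) {
    tau <- exp(log_tau)
    if (any(tau < tau_bounds[1]) || any(tau > tau_bounds[2])) return(Inf)
    vp_solve(runs, schedule, tau[1], tau[2], mode)$rss
  }

  if (is.null(init)) {
    tau1_grid <- schedule$t_open * 2^seq(-3, 3)
    tau2_grid <- schedule$period * 2^seq(1, 9)
  } else {
    tau1_grid <- init$tau1 * 2^seq(-1.5, 1.5, by = 0.5)
    tau2_grid <- init$tau2 * 2^seq(-1.5, 1.5, by = 0.5)
  }
  grid <- expand.grid(tau1 = tau1_grid, tau2 = tau2_grid)
  rss_grid <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    obj(log(c(grid$tau1[i], grid$tau2[i])))
  })
  start <- log(as.numeric(grid[which.min(rss_grid), ]))

  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  tau <- exp(opt$par)
  if (any(tau <= tau_bounds[1] * 1.01) || any(tau >= tau_bounds[2] * 0.99)) {
    abort("Fitted time constant ran into `tau_bounds`.")
  }
  # order the terms fast-first
  if (tau[1] > tau[2]) tau <- rev(tau)
  sol <- vp_solve(runs, schedule, tau[1], tau[2], mode)

  structure(
    list(
      params = transient_params(sol$k1, sol$k2, tau[1], tau[2]),
      per_run_drifts = sol$drifts,
      chi2_min = sol$rss,
      n_points = sol$n_points,
      mode = mode,
      converged = opt$convergence == 0,
      schedule = schedule,
      runs = runs
    ),
    class = "transient_fit"
  )
}

#' @export
print.transient_fit <- function(x, ...) {
  cat("<transient_fit>\n")
  cat(sprintf("  %d run(s), %d points, mode = %s, converged = %s\n",
              nrow(x$runs), x$n_points, x$mode, x$converged))
  p <- x$params
  cat(sprintf("  k1 = %.4g mK/s, tau1 = %.4g s; k2 = %.4g mK/s, tau2 = %.4g s\n",
              p$k1, p$tau1, p$k2, p$tau2))
  cat(sprintf("  chi2_min = %.6g (unit weights)\n", x$chi2_min))
  invisible(x)
}

#' @rdname fit_transient
#' @param x A `transient_fit`.
#' @param ... Unused.
#' @export
tidy.transient_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("k1", "k2", "tau1", "tau2"),
    estimate = c(p$k1, p$k2, p$tau1, p$tau2),
    unit = c("mK/s", "mK/s", "s", "s")
  )
}

#' @rdname fit_transient
#' @export
glance.transient_fit <- function(x, ...) {
  tibble(
    chi2_min = x$chi2_min,
    n_points = x$n_points,
    n_runs = nrow(x$runs),
    mode = x$mode,
    converged = x$converged,
    k1_over_k2 = x$params$k1 / x$params$k2
  )
}

#' Per-sample observed, fitted and residual values of a transient fit
#'
#' @param x A `transient_fit`.
#' @param ... Unused.
#' @return A tibble with one row per sample: `run`, `setting_mAs`,
#'   `time_s`, `observed`, `fitted`, `residual`.
#' @export
augment.transient_fit <- function(x, ...) {
  p <- x$params
  purrr::map_dfr(seq_len(nrow(x$runs)), function(r) {
    wf <- x$runs$waveform[[r]]
    s <- x$runs$setting_mAs[r] / 100
    d <- x$per_run_drifts[r, ]
    fitted <- s * (p$k1 * conv_basis(wf$time_s, p$tau1, x$schedule, x$mode) +
                     p$k2 * conv_basis(wf$time_s, p$tau2, x$schedule, x$mode)) +
      d$slope * wf$time_s + d$offset
    tibble(run = r, setting_mAs = x$runs$setting_mAs[r],
           time_s = wf$time_s, observed = wf$temp_mK,
           fitted = fitted, residual = wf$temp_mK - fitted)
  })
}

#' @export
generics::augment

#' Chi-square-doubling interval of a one-dimensional objective
#'
#' Scans a chi-square function away from its minimiser in both directions
#' until it reaches twice the minimum, and solves for the crossing by root
#' bracketing. This is the interval convention in which a parameter's
#' uncertainty is the deviation that doubles the minimum chi-square.
#'
#' @param chi2_fn Function of one numeric argument returning the
#'   chi-square.
#' @param best The minimiser.
#' @param chi2_min Minimum value (default `chi2_fn(best)`); must be > 0
#'   for doubling to be meaningful.
#' @param lower,upper Scan limits. If the doubling level is not reached
#'   before a limit, that side is reported `NA` (an open interval).
#' @return A list with `lower_dev` (<= 0 or NA), `upper_dev` (>= 0 or NA).
#' @examples
#' chi2_doubling_interval(function(th) 1 + (th - 2)^2, best = 2,
#'                        lower = -10, upper = 10) # devs -1, +1
#' @export
chi2_doubling_interval <- function(chi2_fn, best,
                                   chi2_min = chi2_fn(best),
                                   lower, upper) {
  if (chi2_min <= 0) {
    abort("`chi2_min` must be positive for the doubling criterion.")
  }
  target <- 2 * chi2_min
  g <- function(x) chi2_fn(x) - target

  cross <- function(bound) {
    dir <- sign(bound - best)
    step <- max(abs(best) * 0.01, abs(bound - best) * 1e-4, 1e-12)
    x <- best
    repeat {
      x_next <- x + dir * step
      if ((dir > 0 && x_next >= bound) || (dir < 0 && x_next <= bound)) {
        if (g(bound) < 0) return(NA_real_)
        return(uniroot(g, sort(c(x, bound)), tol = 1e-12)$root)
      }
      if (g(x_next) >= 0) {
        return(uniroot(g, sort(c(x, x_next)), tol = 1e-12)$root)
      }
      x <- x_next
      step <- step * 2
    }
  }
  lo <- cross(lower)
  hi <- cross(upper)
  list(lower_dev = if (is.na(lo)) NA_real_ else lo - best,
       upper_dev = if (is.na(hi)) NA_real_ else hi - best)
}

#' Chi-square-doubling uncertainty of one transient parameter
#'
#' Scans one of `k1`, `k2`, `tau1`, `tau2` away from its best-fit value
#' until the chi-square doubles. The other three transient parameters stay
#' frozen at the best fit; the per-run drift nuisance parameters are by
#' default re-optimised at every scan point (a profile over nuisances
#' only). `profile = "none"` freezes them too (a strict slice).
#'
#' @param fit A converged `transient_fit`.
#' @param param One of `"k1"`, `"k2"`, `"tau1"`, `"tau2"`.
#' @param profile `"drift"` (default) or `"none"`.
#' @param scan_factor Scan limits as a multiplicative range about the best
#'   value (time constants are scanned within
#'   `[best / scan_factor, best * scan_factor]`, weights within
#'   `best * (1 +/- scan_factor)`).
#' @return One-row tibble: `param`, `best_value`, `lower_dev`,
#'   `upper_dev`, `chi2_min`, `open_lower`, `open_upper`.
#' @export
param_uncertainty <- function(fit, param = c("tau1", "tau2", "k1", "k2"),
                              profile = c("drift", "none"),
                              scan_factor = 50) {
  stopifnot(inherits(fit, "transient_fit"))
  param <- match.arg(param)
  profile <- match.arg(profile)
  if (!fit$converged) abort("`fit` did not converge; no interval computed.")

  p <- fit$params
  best <- p[[param]]
  runs <- fit$runs
  sched <- fit$schedule

  chi2_at <- function(theta) {
    q <- p
    q[[param]] <- theta
    if (q$tau1 <= 0 || q$tau2 <= 0) return(Inf)
    total <- 0
    for (r in seq_len(nrow(runs))) {
      wf <- runs$waveform[[r]]
      s <- runs$setting_mAs[r] / 100
      model <- s * (q$k1 * conv_basis(wf$time_s, q$tau1, sched, fit$mode) +
                      q$k2 * conv_basis(wf$time_s, q$tau2, sched, fit$mode))
      resid <- wf$temp_mK - model
      if (profile == "drift") {
        dfit <- stats::lm.fit(cbind(1, wf$time_s), resid)
        total <- total + sum(dfit$residuals^2)
      } else {
        d <- fit$per_run_drifts[r, ]
        total <- total +
          sum((resid - d$slope * wf$time_s - d$offset)^2)
      }
    }
    total
  }

  if (param %in% c("tau1", "tau2")) {
    lims <- c(best / scan_factor, best * scan_factor)
  } else {
    lims <- best + c(-1, 1) * scan_factor * abs(best)
  }
  iv <- chi2_doubling_interval(chi2_at, best, chi2_min = fit$chi2_min,
                               lower = lims[1], upper = lims[2])
  tibble(
    param = param,
    best_value = best,
    lower_dev = iv$lower_dev,
    upper_dev = iv$upper_dev,
    chi2_min = fit$chi2_min,
    open_lower = is.na(iv$lower_dev),
    open_upper = is.na(iv$upper_dev)
  )
}

#' Core (staircase) dose component of a fitted CT response
#'
#' Isolates the slow term of a fitted response — the staircase attributed
#' to heating of the polystyrene core itself, as opposed to the fast
#' thermistor transient — reconstructs its noiseless waveform at the
#' 100 mA·s reference amplitude, extracts the per-cycle temperature rise
#' by midpoint extrapolation, and converts the mean rise to dose. The
#' reconstructed component contains no fast transient, so no settle delay
#' is applied by default.
#'
#' @param fit A converged `transient_fit`.
#' @param schedule Schedule for the reconstruction (default: the fitted
#'   one).
#' @param cp Specific heat capacity, J/(kg K).
#' @param ic_dose_mGy Optional reference chamber dose per cycle per
#'   100 mA·s; when given, the ratio of calorimetric to reference dose is
#'   reported.
#' @param window_fraction,settle_s Passed to [midpoint_cycles()].
#' @return One-row tibble: `mean_delta_T_mK`, `sd_delta_T_mK`, `n_cycles`,
#'   `dose_mGy_per_100mAs`, and (if `ic_dose_mGy` given) `dose_ratio`,
#'   `dose_ratio_rounded`.
#' @export
ps_component_dose <- function(fit, schedule = fit$schedule, cp = 1208,
                              ic_dose_mGy = NULL,
                              window_fraction = 0.5, settle_s = 0) {
  stopifnot(inherits(fit, "transient_fit"))
  if (!fit$converged) abort("`fit` did not converge.")
  check_cp(cp)
  wf <- forward_waveform(fit$params, schedule, component = "slow")
  est <- midpoint_cycles(wf, schedule,
                         window_fraction = window_fraction,
                         settle_s = settle_s)
  out <- tibble(
    mean_delta_T_mK = mean(est$delta_T_mK),
    sd_delta_T_mK = if (nrow(est) > 1) sd(est$delta_T_mK) else 0,
    n_cycles = nrow(est),
    dose_mGy_per_100mAs = dose_from_delta_T(mean(est$delta_T_mK), cp)
  )
  if (!is.null(ic_dose_mGy)) {
    out$dose_ratio <- out$dose_mGy_per_100mAs / ic_dose_mGy
    out$dose_ratio_rounded <- round(out$dose_ratio)
  }
  out
}
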