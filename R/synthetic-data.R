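#' Default irradiation schedules for the two beam regimes
#'
#' `schedule_6mv()` is the megavoltage therapy-beam timing: 60 s on / 60 s
#' off cycles (20 cycles by default). `schedule_ct()` is the CT timing: ten
#' 2 s axial scans at a 10 s period (20 % duty cycle). Both start after one
#' beam-off segment of baseline so that the first cycle has a
#' pre-irradiation window for drift fitting.
#'
#' @param t_open,period,n_cycles,t_start,dt See [irradiation_schedule()].
#' @return An [irradiation_schedule()].
#' @export
schedule_6mv <- function(t_open = 60, period = 120, n_cycles = 20,
                         t_start = period - t_open, dt = 1) {
  irradiation_schedule(t_open, period, n_cycles, t_start, dt)
}

#' @rdname schedule_6mv
#' @export
schedule_ct <- function(t_open = 2, period = 10, n_cycles = 10,
                        t_start = period - t_open, dt = 0.25) {
  irradiation_schedule(t_open, period, n_cycles, t_start, dt)
}

#' Reference ionization-chamber doses
#'
#' The paired reference doses used for linearity checks. For the
#' megavoltage beam: five per-cycle doses (Gy) at nominal dose rates 0.8 to
#' 4.0 Gy/min. For the CT beam: eleven tube current-time settings from 150
#' to 650 mA·s with the chamber-measured 2.46 mGy per cycle per 100 mA·s.
#'
#' @param beam `"6mv"` or `"ct"`.
#' @param ct_mGy_per_100mAs Chamber dose per cycle per 100 mA·s used to
#'   fill the CT table.
#' @return A tibble: for `"6mv"`, columns `dose_rate_Gy_min`,
#'   `ic_dose_Gy`; for `"ct"`, columns `setting_mAs`, `ic_dose_mGy`.
#' @examples
#' reference_doses("6mv")
#' reference_doses("ct")
#' @export
reference_doses <- function(beam = c("6mv", "ct"),
                            ct_mGy_per_100mAs = 2.46) {
  beam <- match.arg(beam)
  if (beam == "6mv") {
    tibble(
      dose_rate_Gy_min = c(0.8, 1.6, 2.4, 3.2, 4.0),
      ic_dose_Gy = c(0.536, 1.07, 1.61, 2.15, 2.69)
    )
  } else {
    settings <- seq(150, 650, by = 50)
    tibble(
      setting_mAs = settings,
      ic_dose_mGy = ct_mGy_per_100mAs * settings / 100
    )
  }
}

#' Table of best-fit transient parameters for the CT response
#'
#' Convenience constructor for the published best-fit response of the
#' prototype in a 120 kV CT beam (per 100 mA·s): a fast thermistor
#' transient (k1 = 0.27 mK/s, tau1 = 1.4 s) atop a slow core staircase
#' (k2 = 0.016 mK/s, tau2 = 628 s).
#'
#' @return A [transient_params()].
#' @export
ct_reference_params <- function() {
  transient_params(k1 = 0.27, k2 = 0.016, tau1 = 1.4, tau2 = 628)
}

add_noise <- function(x, sd, seed) {
  if (sd < 0) abort("Noise standard deviation must be non-negative.")
  if (sd == 0) return(x)
  withr::with_seed(seed, x + rnorm(length(x), mean = 0, sd = sd))
}

#' Simulate a megavoltage staircase run
#'
#' Generates the temperature record of an ideal calorimeter in a
#' high-energy photon beam: during each beam-on interval the temperature
#' rises linearly by `dose_per_cycle_Gy / cp` kelvin; during beam-off it is
#' flat apart from the linear drift. Gaussian white noise of standard
#' deviation `noise_sd_mK` is added per sample, fully determined by
#' `seed`. An optional finite `tau_decay_s` replaces the ideal flat-top
#' staircase by an exponentially relaxing one (heat loss to the phantom);
#' the default is no relaxation, reflecting the negligible excess heat and
#' slow conduction observed in this regime.
#'
#' @param dose_per_cycle_Gy Absorbed dose per cycle, Gy (non-negative).
#' @param schedule An [irradiation_schedule()], nominally [schedule_6mv()].
#' @param cp Specific heat capacity, J/(kg K).
#' @param drift A [drift_params()].
#' @param noise_sd_mK Gaussian noise standard deviation, mK.
#' @param seed Integer seed; identical seeds give identical records.
#' @param tau_decay_s Optional relaxation time constant, s (`Inf` = none).
#' @return A waveform tibble (`time_s`, `temp_mK`).
#' @examples
#' wf <- simulate_6mv_run(1.61, schedule_6mv(), cp = 1212.3, seed = 1)
#' @export
simulate_6mv_run <- function(dose_per_cycle_Gy, schedule,
                             cp = heat_capacity(297.65),
                             drift = drift_params(),
                             noise_sd_mK = 0.005,
                             seed = 1L,
                             tau_decay_s = Inf) {
  if (dose_per_cycle_Gy < 0) abort("`dose_per_cycle_Gy` must be non-negative.")
  check_cp(cp)
  step_mK <- 1000 * dose_per_cycle_Gy / cp
  if (is.finite(tau_decay_s)) {
    pars <- transient_params(k1 = 0, k2 = step_mK / schedule$t_open,
                             tau1 = 1, tau2 = tau_decay_s)
    wf <- forward_waveform(pars, schedule, drift = drift)
  } else {
    t_end <- schedule_end(schedule) + (schedule$period - schedule$t_open)
    t <- seq(0, t_end, by = schedule$dt)
    u <- drift$slope * t + drift$offset
    for (a in pulse_starts(schedule)) {
      ramp <- pmin(pmax((t - a) / schedule$t_open, 0), 1)
      u <- u + step_mK * ramp
    }
    wf <- new_waveform(t, u)
  }
  wf$temp_mK <- add_noise(wf$temp_mK, noise_sd_mK, seed)
  wf
}

#' Simulate a series of CT runs across tube-current settings
#'
#' Generates one waveform per current-time setting via
#' [forward_waveform()]. The transient parameters are understood per
#' 100 mA·s; each run scales both term weights by `setting / 100` (the
#' response shape is dose-rate independent). Drift is per run; noise seeds
#' are derived deterministically from `seed` and the run index.
#'
#' @param settings_mAs Tube current-time products, mA·s (non-empty).
#' @param params_per_100mAs A [transient_params()] per 100 mA·s.
#' @param schedule An [irradiation_schedule()], nominally [schedule_ct()].
#' @param drifts A single [drift_params()] recycled across runs, or a list
#'   with one per run.
#' @param noise_sd_mK Gaussian noise standard deviation, mK.
#' @param seed Integer seed.
#' @return A tibble with columns `setting_mAs` and `waveform` (a
#'   list-column of waveform tibbles).
#' @examples
#' runs <- simulate_ct_series(c(150, 400, 650), ct_reference_params(),
#'                            schedule_ct(), seed = 7)
#' @export
simulate_ct_series <- function(settings_mAs,
                               params_per_100mAs = ct_reference_params(),
                               schedule = schedule_ct(),
                               drifts = drift_params(),
                               noise_sd_mK = 0.002,
                               seed = 1L) {
  if (length(settings_mAs) == 0) abort("`settings_mAs` must be non-empty.")
  if (inherits(drifts, "drift_params")) {
    drifts <- rep(list(drifts), length(settings_mAs))
  }
  if (length(drifts) != length(settings_mAs)) {
    abort("`drifts` must be one drift_params or one per setting.")
  }
  p <- params_per_100mAs
  wfs <- purrr::map2(settings_mAs, seq_along(settings_mAs), function(s, i) {
    scaled <- transient_params(p$k1 * s / 100, p$k2 * s / 100, p$tau1, p$tau2)
    wf <- forward_waveform(scaled, schedule, drift = drifts[[i]])
    wf$temp_mK <- add_noise(wf$temp_mK, noise_sd_mK,
                            seed = (seed * 1000L + i) %% .Machine$integer.max)
    wf
  })
  tibble(setting_mAs = settings_mAs, waveform = wfs)
}

#' Rescale a CT run to the 100 mA·s reference amplitude
#'
#' Overlay convention for comparing runs at different tube currents: the
#' whole record is multiplied by `100 / setting_mAs`.
#'
#' @param waveform A waveform tibble.
#' @param setting_mAs The run's current-time product, mA·s.
#' @return A waveform tibble.
#' @export
normalize_to_100mAs <- function(waveform, setting_mAs) {
  waveform <- as_waveform(waveform)
  if (setting_mAs <= 0) abort("`setting_mAs` must be positive.")
  waveform$temp_mK <- waveform$temp_mK * 100 / setting_mAs
  waveform
}

#' Write a set of simulated runs with a provenance manifest
#'
#' Writes one waveform CSV per run plus a `manifest.yaml` recording the
#' seed, schedule, generator parameters, and file-to-setting mapping, so a
#' fixture set is fully reproducible from its manifest.
#'
#' @param runs A tibble with a `waveform` list-column and either
#'   `setting_mAs` or `ic_dose_Gy` identifying each run.
#' @param dir Output directory (created if needed).
#' @param schedule The [irradiation_schedule()] used.
#' @param seed The generator seed.
#' @param params Optional named list of generator parameters to record.
#' @return The manifest path, invisibly.
#' @export
write_run_fixtures <- function(runs, dir, schedule, seed, params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id_col <- intersect(c("setting_mAs", "ic_dose_Gy"), names(runs))[1]
  if (is.na(id_col)) abort("`runs` needs a `setting_mAs` or `ic_dose_Gy` column.")
  files <- sprintf("run_%02d.csv", seq_len(nrow(runs)))
  purrr::walk2(runs$waveform, files,
               ~ write_waveform_csv(.x, file.path(dir, .y)))
  manifest <- list(
    seed = seed,
    schedule = unclass(schedule),
    params = params,
    runs = purrr::map2(files, runs[[id_col]],
                       ~ setNames(list(.x, .y), c("file", id_col)))
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
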