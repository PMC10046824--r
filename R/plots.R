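#' Plot a temperature waveform
#'
#' Line plot of a temperature record; when a schedule is supplied the
#' beam-on intervals are shaded.
#'
#' @param waveform A waveform tibble (`time_s`, `temp_mK`).
#' @param schedule Optional [irradiation_schedule()].
#' @return A ggplot object.
#' @export
plot_waveform <- function(waveform, schedule = NULL) {
  waveform <- as_waveform(waveform)
  p <- ggplot2::ggplot(waveform,
                       ggplot2::aes(x = .data$time_s, y = .data$temp_mK))
  if (!is.null(schedule)) {
    shade <- tibble(
      xmin = pulse_starts(schedule),
      xmax = pulse_starts(schedule) + schedule$t_open
    )
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85")
  }
  p + ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "temperature (mK)")
}

#' @export
autoplot.dose_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$reference_dose,
                               y = .data$calorimeter_dose)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "reference (IC) dose", y = "calorimeter dose",
      title = sprintf("slope = %.4f (%+.2f%% from unity)",
                      object$slope, 100 * object$slope_dev_from_unity))
}

#' @export
autoplot.transient_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        size = 0.4, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                       colour = "firebrick") +
    ggplot2::facet_wrap(~ setting_mAs, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "temperature (mK)")
}
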