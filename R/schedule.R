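#' Irradiation schedule
#'
#' Describes a train of `n_cycles` rectangular beam pulses: each cycle is
#' `t_open` seconds of beam-on followed by `period - t_open` seconds of
#' beam-off, the first pulse starting at `t_start`. `dt` is the sample
#' spacing of records acquired under the schedule. The duty cycle is
#' `t_open / period` (20 % for the CT runs: 2 s on / 8 s off).
#'
#' @param t_open Beam-on time per cycle, s; `0 < t_open < period`.
#' @param period Cycle period, s.
#' @param n_cycles Number of cycles (positive integer).
#' @param t_start Start time of the first pulse, s.
#' @param dt Sample spacing, s.
#' @return An object of class `irradiation_schedule`.
#' @examples
#' ct_schedule <- irradiation_schedule(t_open = 2, period = 10,
#'                                     n_cycles = 10, dt = 0.25)
#' @export
irradiation_schedule <- function(t_open, period, n_cycles,
                                 t_start = 0, dt = 0.25) {
  if (!(t_open > 0 && t_open < period)) {
    abort("Need 0 < t_open < period.")
  }
  if (n_cycles < 1 || n_cycles != round(n_cycles)) {
    abort("`n_cycles` must be a positive integer.")
  }
  if (dt <= 0) abort("`dt` must be positive.")
  structure(
    list(t_open = t_open, period = period, n_cycles = as.integer(n_cycles),
         t_start = t_start, dt = dt),
    class = "irradiation_schedule"
  )
}

#' @export
print.irradiation_schedule <- function(x, ...) {
  cat(sprintf(
    "<irradiation_schedule> %g s on / %g s off x %d cycles (duty %.0f%%), t_start = %g s, dt = %g s\n",
    x$t_open, x$period - x$t_open, x$n_cycles,
    100 * x$t_open / x$period, x$t_start, x$dt))
  invisible(x)
}

schedule_end <- function(schedule) {
  schedule$t_start + schedule$n_cycles * schedule$period
}

#' Beam timing function f(t)
#'
#' Unit-height square wave with zero baseline: 1 when the beam is on, 0
#' otherwise. Beam-on windows are half-open,
#' `[t_start + m * period, t_start + m * period + t_open)` for
#' `m = 0, ..., n_cycles - 1` (on at the leading edge).
#'
#' @param t Time(s), s.
#' @param schedule An [irradiation_schedule()].
#' @return Numeric vector of 0/1, same length as `t`.
#' @examples
#' s <- irradiation_schedule(2, 10, 10)
#' timing_function(c(0.5, 5), s) # 1, 0
#' @export
timing_function <- function(t, schedule) {
  stopifnot(inherits(schedule, "irradiation_schedule"))
  rel <- t - schedule$t_start
  m <- floor(rel / schedule$period)
  phase <- rel - m * schedule$period
  on <- rel >= 0 & m < schedule$n_cycles & phase < schedule$t_open
  as.numeric(on)
}

# Pulse start times of the schedule.
pulse_starts <- function(schedule) {
  schedule$t_start + (seq_len(schedule$n_cycles) - 1) * schedule$period
}
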