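#' Heat-capacity model for the polystyrene core
#'
#' The specific heat capacity of polystyrene is described by the empirical
#' relation
#' \deqn{C_p(T) = \frac{1000}{M}\left(a T^{-2} + b T + c\right)}
#' with \eqn{T} the absolute temperature in kelvin, \eqn{M} the molar mass
#' in g/mol and \eqn{a, b, c} empirical coefficients. With the default
#' constants, \eqn{C_p} is returned in J/(kg K) and is positive and strictly
#' increasing over ordinary laboratory temperatures.
#'
#' @param molar_mass_g_per_mol Molar mass of the repeat unit, g/mol.
#' @param coeff_a,coeff_b,coeff_c Empirical coefficients of the relation
#'   above (units such that each term is in K when multiplied out).
#'
#' @return An object of class `heat_capacity_model`.
#' @examples
#' m <- heat_capacity_model()
#' heat_capacity(297.65, m) # ~1212.4 J/(kg K) at 24.5 degC
#' @export
heat_capacity_model <- function(molar_mass_g_per_mol = 104.15,
                                coeff_a = 7.755e5,
                                coeff_b = 0.5345,
                                coeff_c = -41.58) {
  if (!is.numeric(molar_mass_g_per_mol) || molar_mass_g_per_mol <= 0) {
    abort("`molar_mass_g_per_mol` must be a positive number.")
  }
  structure(
    list(
      molar_mass_g_per_mol = molar_mass_g_per_mol,
      coeff_a = coeff_a,
      coeff_b = coeff_b,
      coeff_c = coeff_c
    ),
    class = "heat_capacity_model"
  )
}

#' @export
print.heat_capacity_model <- function(x, ...) {
  cat("<heat_capacity_model>\n")
  cat(sprintf("  M = %g g/mol; a = %g, b = %g, c = %g\n",
              x$molar_mass_g_per_mol, x$coeff_a, x$coeff_b, x$coeff_c))
  invisible(x)
}

#' Specific heat capacity at an absolute temperature
#'
#' Evaluates the polystyrene heat-capacity relation (see
#' [heat_capacity_model()]) at one or more absolute temperatures.
#'
#' @param temperature_K Absolute temperature(s) in kelvin; must be positive.
#' @param model A [heat_capacity_model()].
#' @return Specific heat in J/(kg K), same length as `temperature_K`.
#' @examples
#' heat_capacity(293.15)
#' @export
heat_capacity <- function(temperature_K, model = heat_capacity_model()) {
  stopifnot(inherits(model, "heat_capacity_model"))
  if (!is.numeric(temperature_K) || any(!is.finite(temperature_K)) ||
      any(temperature_K <= 0)) {
    abort("`temperature_K` must be positive and finite (absolute kelvin).")
  }
  1000 / model$molar_mass_g_per_mol *
    (model$coeff_a / temperature_K^2 +
       model$coeff_b * temperature_K +
       model$coeff_c)
}

#' Convert a temperature rise to absorbed dose (and back)
#'
#' Absorbed dose in the core is the temperature rise times the specific
#' heat capacity: `dose = cp * delta_T`. Because Gy = J/kg, the same
#' numeric relation holds in kelvin-to-gray and millikelvin-to-milligray;
#' supply `delta_T` in K to get Gy, or in mK to get mGy.
#'
#' @param delta_T Temperature rise (K or mK).
#' @param cp Specific heat capacity in J/(kg K); must be positive.
#' @return `dose_from_delta_T()`: absorbed dose (Gy or mGy).
#' @examples
#' dose_from_delta_T(3.0e-5, 1208) # 0.0362 Gy
#' delta_T_from_dose(1, 1208)      # ideal slope, mK per mGy
#' @export
dose_from_delta_T <- function(delta_T, cp) {
  check_cp(cp)
  cp * delta_T
}

#' @param dose Absorbed dose (Gy or mGy).
#' @return `delta_T_from_dose()`: temperature rise (K or mK).
#' @rdname dose_from_delta_T
#' @export
delta_T_from_dose <- function(dose, cp) {
  check_cp(cp)
  dose / cp
}

check_cp <- function(cp) {
  if (!is.numeric(cp) || length(cp) != 1L || !is.finite(cp) || cp <= 0) {
    abort("`cp` must be a single positive finite number (J/(kg K)).")
  }
  invisible(cp)
}

#' Effective heat-conduction length from diffusivity and time constant
#'
#' A thermal time constant \eqn{\tau} together with a thermal diffusivity
#' \eqn{\delta} sets the spatial scale over which heat diffuses,
#' \eqn{r = \sqrt{\delta\tau}} (the dimensionally consistent diffusion
#' length). For polystyrene (\eqn{\delta \approx 10^{-7}} m^2/s) and a slow
#' time constant of several hundred seconds this is of order the core
#' radius.
#'
#' @param diffusivity_m2_s Thermal diffusivity, m^2/s (non-negative).
#' @param time_constant_s Thermal time constant, s (non-negative).
#' @return Length in metres.
#' @examples
#' effective_thermal_length(1.0e-7, 628) # ~8 mm
#' @export
effective_thermal_length <- function(diffusivity_m2_s, time_constant_s) {
  if (any(diffusivity_m2_s < 0) || any(time_constant_s < 0)) {
    abort("Diffusivity and time constant must be non-negative.")
  }
  sqrt(diffusivity_m2_s * time_constant_s)
}

#' Excess-heat factor of a measured dose-response slope
#'
#' The ideal calorimetric response of the core alone is
#' `delta_T_from_dose(1, cp)` millikelvin per milligray. A measured slope
#' (mK of temperature rise per mGy of reference ionization-chamber dose)
#' larger than this indicates excess heat: radiation heating of sensor and
#' wire materials inflating the signal above the dose-to-core contribution.
#' The factor is the ratio of the measured to the ideal slope.
#'
#' @param measured_slope_mK_per_mGy Measured slope, mK per mGy.
#' @param cp Specific heat capacity, J/(kg K).
#' @param rounded If `TRUE`, round to the nearest integer for presentation;
#'   the default reports the raw ratio.
#' @return Dimensionless excess-heat factor.
#' @examples
#' excess_heat_factor(0.0139, 1208) # ~16.8
#' @export
excess_heat_factor <- function(measured_slope_mK_per_mGy, cp,
                               rounded = FALSE) {
  check_cp(cp)
  if (any(measured_slope_mK_per_mGy <= 0)) {
    abort("`measured_slope_mK_per_mGy` must be positive.")
  }
  ideal <- delta_T_from_dose(1, cp) # mK per mGy
  f <- measured_slope_mK_per_mGy / ideal
  if (isTRUE(rounded)) round(f) else f
}
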