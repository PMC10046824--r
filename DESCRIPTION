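Package: calodose
Title: Calorimetric Dose Analysis for Pulsed Photon and CT X-Ray Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for portable polystyrene-core radiation
    calorimetry. Provides the material thermal constants and
    temperature-to-dose conversions for a polystyrene core, a forward model
    of the thermistor temperature response to pulsed irradiation (a
    two-exponential impulse response convolved with the beam timing
    function, plus linear drift), seeded synthetic-waveform generators for
    megavoltage staircase records and kilovoltage CT transient records, and
    three extraction methods that convert micro-kelvin temperature records
    into absorbed dose: per-cycle midpoint extrapolation, chi-square fitting
    of the convolution model with profile-scan uncertainty intervals, and
    frequency-domain analysis of the fundamental duty-cycle harmonic.
    Includes linearity regression against reference ionization-chamber
    doses and excess-heat diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
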