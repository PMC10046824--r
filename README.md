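# calodose

Calorimetric dose analysis for pulsed photon and CT X-ray beams.

A portable calorimeter with a small polystyrene (PS) core and embedded
thermistors measures absorbed dose directly: ionizing radiation deposits
energy in the core, the core warms by a few millikelvin (or, in CT beams,
tens of microkelvin), and the dose follows from the temperature rise and
the core's specific heat capacity, since Gy = J/kg. `calodose` implements
the analysis chain for such an instrument, for medical physicists and
metrologists working on calorimetric dose standards:

- **Thermal constants and conversions** — the empirical PS heat-capacity
  relation
  `Cp(T) = 1000/M (a T⁻² + b T + c)` (J/(kg·K)), dose ↔ temperature-rise
  conversion, diffusion-length estimates `r = sqrt(δτ)`, and excess-heat
  factors.
- **Forward waveform model** — the semi-empirical thermistor response
  `u(t) = (k₁ e^(−t/τ₁) + k₂ e^(−t/τ₂)) ∗ f(t)` (convolution of a
  two-exponential impulse response with the beam timing square wave
  `f(t)`), plus per-run linear drift. The convolution is evaluated in
  closed form per pulse; a rectangle-rule discrete mode exists for
  replicating legacy numerics.
- **Synthetic-data generators** — seeded megavoltage "staircase" records
  (linear heating during 60 s beam-on cycles) and CT records (a fast
  thermistor transient atop a small core staircase, 2 s on / 8 s off at
  eleven tube-current settings), with reference ionization-chamber dose
  tables.
- **Three extraction methods** —
  1. *midpoint extrapolation*: per-cycle temperature rise from pre/post
     baseline fits extrapolated to the pulse midpoint, exactly invariant
     to linear drift;
  2. *time-domain transient fitting*: unit-weight chi-square fit of the
     convolution model with shared response parameters across dose rates
     and per-run drift nuisances, chi-square-doubling uncertainty
     intervals, and isolation of the core (staircase) dose component;
  3. *frequency-domain analysis*: the per-cycle rise from the FFT
     fundamental at the duty-cycle frequency,
     `amp = A · t_open/(nπ) · sinc(nπ t_open/period)`.
- **Linearity and excess-heat diagnostics** — ordinary least-squares
  regression of calorimeter against chamber dose, slope deviation from
  unity, and the ratio of a measured response slope to the ideal
  core-only slope `1/Cp` mK/mGy.

Everything is tidyverse-native: waveforms are tibbles
(`time_s`, `temp_mK`), results are tibbles, fitted objects support
`tidy()`, `glance()`, `augment()` and `autoplot()`.

## Worked example

Recover a megavoltage dose by midpoint extrapolation:

```r
library(calodose)

cp <- heat_capacity(297.65)      # 1212.4 J/(kg K) at 24.5 degC
sched <- schedule_6mv()          # 60 s on / 60 s off, 20 cycles
wf <- simulate_6mv_run(1.61, sched, cp = cp,
                       drift = drift_params(2e-4, 0.1),
                       noise_sd_mK = 0.005, seed = 42)
run_dose(midpoint_cycles(wf, sched), cp)
#>   mean_delta_T_mK sd_delta_T_mK n_cycles dose_Gy sd_dose_Gy
#> 1           1.327      0.007676       20   1.609   0.009307
```

The mean per-cycle rise of 1.327 mK times 1212.4 J/(kg·K) gives
1.609 Gy — the generating 1.61 Gy chamber dose back within 0.1 %, with a
cycle-to-cycle spread of 9 mGy.

Fit the CT transient model across three tube-current settings and isolate
the core dose component:

```r
runs <- simulate_ct_series(c(150, 400, 650), seed = 7)
fit <- fit_transient(runs, schedule_ct(), init = ct_reference_params())
fit
#> <transient_fit>
#>   3 run(s), 1395 points, mode = analytic, converged = TRUE
#>   k1 = 0.27 mK/s, tau1 = 1.4 s; k2 = 0.01598 mK/s, tau2 = 632.5 s
#>   chi2_min = 0.00540356 (unit weights)

ps_component_dose(fit, cp = 1208, ic_dose_mGy = 2.46)
#>   mean_delta_T_mK n_cycles dose_mGy_per_100mAs dose_ratio
#> 1          0.0320       10                38.6       15.7
```

The fitted fast term (k₁ ≈ 0.27 mK/s, τ₁ ≈ 1.4 s) is the thermistor
transient; the slow term (k₂ ≈ 0.016 mK/s, τ₂ ≈ 630 s) is the staircase
heating of the PS core itself. The isolated staircase rises 0.032 mK per
cycle per 100 mA·s, i.e. 38.6 mGy — roughly 16 times the 2.46 mGy the
ionization chamber reports, the signature of excess heat deposited in the
high-atomic-number sensor materials at CT beam energies.

## Package layout

| Area | Functions |
| --- | --- |
| thermal constants | `heat_capacity()`, `dose_from_delta_T()`, `effective_thermal_length()`, `excess_heat_factor()` |
| forward model | `irradiation_schedule()`, `timing_function()`, `transient_params()`, `forward_waveform()` |
| generators | `simulate_6mv_run()`, `simulate_ct_series()`, `reference_doses()`, `write_run_fixtures()` |
| midpoint analysis | `extrapolate_midpoint()`, `midpoint_cycles()`, `run_dose()`, `linear_calibration()` |
| transient fitting | `fit_transient()`, `param_uncertainty()`, `chi2_doubling_interval()`, `ps_component_dose()` |
| spectral analysis | `fundamental_amplitude()`, `rate_from_amplitude()`, `spectral_estimate()`, `dose_response()` |
| pipelines | `read_manifest()`, `run_pipeline()` |

See the methods vignette (`vignettes/calorimetric-dose-analysis.Rmd`) for
the model, its assumptions, and the numerical choices.
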