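---
title: "Methods: calorimetric dose analysis for pulsed and CT X-ray beams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calorimetric dose analysis for pulsed and CT X-ray beams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calodose)
```

## The measurement problem

A polystyrene-core calorimeter realizes absorbed dose directly: radiation
deposits energy in the core, the core warms, and dose follows from
`dose = Cp · ΔT` because gray is joule per kilogram. The same numeric
relation holds in mK → mGy, which is the working scale of the package
(time in s, temperature differences in mK, absolute temperature in K,
dose in mGy; unit conversion happens only at interfaces).

Two beam regimes behave very differently:

* **Megavoltage therapy beams** (per-cycle doses of order 1 Gy). The core
  and sensors absorb nearly alike, heat transfer over a 60 s cycle is
  mild, and the record is a noisy *staircase*: temperature ramps linearly
  while the beam is on and is flat (apart from ambient drift) while it is
  off.
* **Kilovoltage CT beams** (per-cycle doses of order 10 mGy).
  Photoelectric absorption in the high-atomic-number thermistor bead
  deposits far more energy per unit mass than in the polystyrene, so each
  2 s scan produces a large, fast rise-and-decay transient in the sensor
  reading that buries the small core staircase. Quantifying that excess
  heat, and extracting the core component underneath it, is the central
  analysis task.

## The forward model

The temperature record is modelled semi-empirically as

$$u(t) = \left(k_1 e^{-t/\tau_1} + k_2 e^{-t/\tau_2}\right) * f(t)
  \;+\; \mathrm{slope}\cdot t + \mathrm{offset},$$

where `f(t)` is the unit-height beam timing square wave (half-open
beam-on windows, on at the leading edge) and `*` is convolution. The
fast term (k₁, τ₁) is Newton's-law conduction from the thermistor bead
into the surrounding core; the slow term (k₂, τ₂) is the core staircase
relaxing toward the phantom. This form deliberately stops short of a
physical heat-equation solution: it is the minimal response shape that
separates "sensor transient" from "core heating", and its parameters are
empirical.

Because `f` is a sum of boxcars, the convolution has a closed form per
pulse: during a pulse starting at `a`,
`kτ(1 − e^{−(t−a)/τ})`, and after it,
`kτ(e^{w/τ} − 1)e^{−(t−a)/τ}` (computed with `expm1` so the τ → ∞
staircase limit is exact). `forward_waveform()` sums these segments; this
*analytic* mode is the default and is exact at any sample spacing.

A *discrete* mode instead convolves the sampled kernel and timing
function by a right-endpoint rectangle rule on the `dt` grid. It
systematically underestimates the integral at coarse `dt` and converges
to the analytic mode as `dt → 0`; it exists to replicate analyses that
used grid convolution at the experimental 0.25 s sampling. A
multiplicative `compensation` factor on (k₁, k₂) is available for such
replication. Its default is 1 (no compensation): the rectangle-rule
deficit depends on the time constant (about 9 % on a 1.4 s transient at
0.25 s sampling, negligible on a 628 s staircase), so no single factor
corrects it, and published single-factor compensations tied to a specific
legacy quadrature (e.g. 1/0.82) are not reproduced as defaults.

## What the generators emulate — and what they do not

`simulate_6mv_run()` produces the megavoltage regime: per-cycle step
`1000 · dose/Cp` mK, piecewise-linear ramps, linear drift, white Gaussian
noise. `simulate_ct_series()` produces CT series: the forward model with
weights scaled by `setting/100` (the response shape is dose-rate
independent; amplitudes are per 100 mA·s), one waveform per tube-current
setting, per-run drift.

Default study conditions, chosen once:

| quantity | default | basis |
| --- | --- | --- |
| 6 MV timing | 60 s on / 60 s off, 20 cycles, dt = 1 s | staircase experiment design |
| CT timing | 2 s on / 8 s off, 10 cycles, dt = 0.25 s | ten 2 s axial scans, 20 % duty |
| lead-in baseline | one off-segment before the first pulse | gives cycle 1 a pre-fit window |
| CT response / 100 mA·s | k₁ = 0.27, k₂ = 0.016 mK/s; τ₁ = 1.4, τ₂ = 628 s | published best-fit values |
| reference doses | 0.536–2.69 Gy (6 MV); 2.46 mGy / cycle / 100 mA·s, 150–650 mA·s (CT) | chamber measurements |
| noise σ | 0.005 mK (6 MV), 0.002 mK (CT) | consistent with micro-kelvin readout sensitivity; free parameters of the tests, not measured values |
| drift | slope 2×10⁻⁴ mK/s, offset 0.1 mK in fixtures | "small relative to signal" ambient drift |

The generators target waveform *statistics* only. They do not model
scanner geometry, bowtie filtration, spectra, water convection,
heat-equation conduction within the core, or correlated (1/f) readout
noise — so passing recovery tests demonstrates correctness of the
estimators under the declared noise model, not robustness to every
artifact of real records. Two published dose statements for the CT beam
(about 8.6 mGy per 2 s scan at 350 mA, versus 2.46 mGy per cycle per
100 mA·s) are plausibly different quantities (air kerma versus dose in
phantom); the generators use 2.46 mGy/100 mA·s throughout and the
discrepancy is noted, not resolved.

## Midpoint extrapolation

For each cycle, straight lines are fitted to the beam-off segment before
the pulse and after it, both are evaluated at the temporal midpoint of
the beam-on interval, and ΔT is their difference. Any global linear
drift adds identically to both lines at the same instant, so the
estimate is *exactly* drift-invariant (this is a property test, at
machine precision).

Windows are the genuinely open design choice; the package fixes:

* pre-fit on the trailing 50 % of the preceding off-segment, post-fit on
  the leading 50 % of the following off-segment (`window_fraction = 0.5`
  balances noise averaging against curvature from slow relaxation);
* an optional `settle_s` delay before the post-window for records that
  contain a fast transient (about 5 τ₁ is appropriate in the CT regime;
  the 6 MV regime needs none);
* cycle boundaries come from the declared schedule, never from edge
  detection — the schedule is known in both experiments;
* windows with fewer than 3 samples are an error, not a silent NA.

Run-level summaries average cycles; the quoted spread is the standard
deviation over cycles (flagged, and reported as 0, for a single cycle).
Linearity against chamber dose uses ordinary least squares with a free
intercept — weighting across dose rates is deliberately not applied, and
the headline number is the slope's deviation from unity.

## Transient fitting

`fit_transient()` minimises the unit-weight residual sum of squares over
shared (k₁, k₂, τ₁, τ₂) and per-run (slope, offset). Unit weights are
structural: the chi-square-doubling uncertainty convention presupposes an
unnormalised objective, and no per-point σ is available. Two numerical
facts shape the optimizer:

1. the model is *linear* in k₁, k₂ and every drift parameter, so at any
   candidate (τ₁, τ₂) those are solved exactly by least squares
   (variable projection);
2. the two time constants differ by a factor of ~450, which defeats
   naive joint gradient starts.

The outer 2-D search over (log τ₁, log τ₂) therefore runs a coarse
logarithmic grid followed by a Nelder–Mead simplex — derivative-free,
deterministic, and convergent to ≤ 0.1 % on noiseless records. τ values
are kept fast-first by ordering; a fit that runs into the τ bounds is an
error, and non-convergence is a flag, never silent. The time constants
are shared across runs in a series (the fit does not refit τ per dose
rate); this is the stronger reading of dose-rate independence and is the
package's choice where the convention was ambiguous.

Parameter uncertainty follows the chi-square-doubling convention: one
parameter is scanned from its best value until χ² reaches 2·χ²_min
(geometric stepping, then root bracketing with `uniroot`). The other
transient parameters stay frozen; the drift nuisances are re-optimised at
every scan point (a profile over nuisances only), with a strict-slice
option (`profile = "none"`) since the published convention is ambiguous —
the slice can only be narrower. A side on which doubling is not reached
within the scan bounds is returned `NA` and flagged open.

`ps_component_dose()` reconstructs the isolated slow (core staircase)
term at 100 mA·s, runs midpoint extrapolation on it, and converts the
mean rise to dose. The reconstructed component contains no fast
transient, so no settle delay is applied to it. On the published
best-fit parameters this yields 0.0320 mK per cycle — essentially
k₂·t_open, because midpoint extrapolation cancels the slow relaxation
like a local drift — slightly above the ~0.030 mK quoted from real-data
reconstructions; the difference (≈ 7 %) is within the spread of that
estimate.

## Frequency-domain analysis

For an ideal staircase heating at rate `A` mK/s during `t_open` of each
`period`, the one-sided amplitude of harmonic `n` of the detrended
record is

$$\mathrm{amp} = A\,\frac{t_\mathrm{open}}{n\pi}\,
  \mathrm{sinc}\!\left(\frac{n\pi\,t_\mathrm{open}}{period}\right),
  \qquad \mathrm{sinc}(x) = \sin x / x .$$

`fundamental_amplitude()` fixes the conventions:

* DFT normalisation is one-sided `2|X_k|/N`, recorded in pipeline
  output metadata; the inversion above absorbs any constant, so the
  choice only has to be applied uniformly.
* The bin is located from the schedule (`k = n · n_cycles` for an
  integer-cycle record), never by peak search — immune to drift leakage
  into neighbouring bins.
* The record is trimmed to the integer-cycle window and the linear
  detrend is fitted *within that window*. A trend mismatch of slope `m`
  leaks an amplitude of order `m·T/(πk)` into bin `k`; fitting the trend
  over a longer record (lead-in and trailing baseline included) leaves
  exactly such a mismatch and biases the fundamental by a few percent,
  while window-fitting keeps the staircase oracle agreement within 1 %.
* Inversion at a sinc zero (duty-cycle multiples, e.g. harmonic 5 of a
  20 % duty cycle) is an error; `sinc(0) = 1` handles the
  continuous-beam limit.

At the experimental 0.25 s sampling, harmonic `n` carries a known
discrete-integration excess of `(x/\sin x)^2` with
`x = nπ\,dt/period` (+0.2 % at n = 1, +2.3 % at n = 3); cross-harmonic
consistency is therefore a property of well-resolved records, while
fundamental-based estimates at dt = 0.25 s stay within 1 % of the
time-domain oracle.

The excess-heat factor of a fitted rise-versus-chamber-dose slope is its
ratio to the ideal core-only slope `1/Cp` mK/mGy. Raw ratios are
reported; integer presentation rounding is an explicit flag, never the
stored value. Note that the frequency- and time-domain diagnostics answer
different questions — the FFT fundamental of a *full* CT record is
dominated by the thermistor transient, while the staircase-component
dose isolates the core term — so their factors are reported side by side
without being forced to agree.

## Other numerical and design choices

* The diffusion-length relation is implemented as `r = sqrt(δτ)`: it is
  the dimensionally consistent form, and it is the form that reproduces
  the ~8 mm (τ = 628 s) and ~0.4 mm (τ = 1.4 s) scales from
  δ = 10⁻⁷ m²/s.
* All randomness flows through explicit integer seeds
  (`withr::with_seed`); generators never touch the global RNG stream,
  and per-run seeds are derived arithmetically from the series seed.
* Waveforms serialize as plain CSV (`time_s,temp_mK`); pipeline runs are
  driven by a YAML manifest whose hash is embedded in every JSON summary,
  so any output is reproducible bit for bit from manifest + seed.
* Degenerate inputs fail loudly: non-positive absolute temperatures,
  non-positive Cp, unresolved pulses (`dt ≥ t_open`), empty run lists,
  all-equal reference doses, records shorter than one period.

Problem sizes in the test suite and acceptance script are the study
conditions themselves (20-cycle megavoltage runs of ~2500 samples;
10-cycle CT runs of ~450 samples; series of 1–11 settings; parameter
recovery medians over 5–50 seeded fixtures) — small enough that the full
suite runs in well under a minute while exercising every estimator at
realistic signal-to-noise.

## Known limitations

* The two-exponential response is semi-empirical; no finite-element or
  heat-equation impulse response is offered, and model misfit on real
  records will widen chi-square-doubling intervals in ways white-noise
  simulations do not show.
* Published real-data slopes (the 1.6 %/1.2 % megavoltage deviations,
  the 0.0139 mK/mGy CT spectral slope) are detector measurements; the
  package uses them as inputs to factor arithmetic and as synthetic-bias
  fixtures, not as quantities it can re-derive.
* Drift is strictly linear per run; higher-order baselines, convection
  artifacts, and correlated noise are out of scope.
* The thermistor diffusivity is only assumed comparable to polystyrene
  when interpreting τ₁ as a ~0.4 mm conduction length.
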