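# Shared study-condition fixtures.

# Independent sinc used when checking spectral relations.
sinc_ref <- function(x) ifelse(x == 0, 1, sin(x) / x)

cp_ref <- function() heat_capacity(297.65) # 24.5 degC

# Published best-fit CT response and the two experiment timings.
tbl1 <- function() ct_reference_params()

# A slowly drifting baseline typical of the runs.
small_drift <- function() drift_params(slope = 2e-4, offset = 0.1)

# Noiseless ideal staircase (slow term only, effectively no relaxation).
ideal_staircase <- function(rate_mK_s = 0.015, schedule = schedule_ct()) {
  forward_waveform(
    transient_params(k1 = 0, k2 = rate_mK_s, tau1 = 1, tau2 = 1e9),
    schedule, component = "slow"
  )
}
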