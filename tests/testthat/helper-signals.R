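# Shared fixtures, all generated in code.

# Unit-peak biexponential bump evaluated on a time grid.
biexp_bump <- function(t, onset, amplitude, tau_rise = 0.7, tau_decay = 2.0) {
  tau <- t - onset
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  pk <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  v <- exp(-tau / tau_decay) - exp(-tau / tau_rise)
  v[tau < 0] <- 0
  amplitude * v / pk
}

# Clean phasic trace with SCRs at given onsets/amplitudes.
clean_phasic <- function(duration_s, fs, onsets, amplitudes) {
  t <- (0:(duration_s * fs - 1)) / fs
  out <- numeric(length(t))
  for (j in seq_along(onsets))
    out <- out + biexp_bump(t, onsets[j], amplitudes[j])
  out
}

# A minimal one-site simulation config for clean ground-truth tests.
clean_sim_config <- function(..., label = "finger", gain = 1,
                             responsiveness = 1, noise = 0,
                             drift = 0, spont = 0, seed = 1) {
  simulation_config(
    n_subjects = 1,
    site_profiles = list(site_profile(label, gain = gain,
                                      tonic_level_us = 5,
                                      tonic_drift_sd = drift,
                                      responsiveness = responsiveness,
                                      spontaneous_scr_rate_per_min = spont)),
    measurement_noise_sd_us = noise,
    tonic_level_subject_cv = 0,
    seed = seed, ...)
}

# Dense convolution operator matching the solver's recursive kernel exactly.
kernel_matrix <- function(kern, n) {
  vapply(seq_len(n), function(j) {
    e <- numeric(n); e[j] <- 1
    kernel_convolve(kern, e)
  }, numeric(n))
}

expect_no_error <- function(expr) expect_error(expr, NA)
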