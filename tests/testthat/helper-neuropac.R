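# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# Carrier amplitude (in background-SD units) that places an injected burst
# peak at `k` envelope SDs above the band envelope mean, calibrated on a
# noise-only recording with the same spec.
calibrate_band_amp <- function(band, fs = 2000, k = 5, noise_sd = 15,
                               seed = 777) {
  noise <- gen_lfp(lfp_spec(fs = fs, duration_s = 60, n_channels = 1,
                            noise_sd = noise_sd), seed = seed)$signal
  env <- Mod(analytic_signal(bandpass(noise, band)$data[, 1]))
  (mean(env) + k * stats::sd(env)) / noise_sd
}

# One-channel recording with n_ev injected bursts of the given kind.
make_burst_sim <- function(kind = "ripple", carrier = 160,
                           duration_ms = 50, n_ev = 20, fs = 2000,
                           amp_mult, seed = 1, duration_s = 60) {
  t_ons <- seq(2, duration_s - 4, length.out = n_ev)
  evs <- lapply(t_ons, function(t0) {
    event_spec(kind, t0, duration_ms / 1000, carrier, amp_mult, 1)
  })
  sim <- gen_lfp(lfp_spec(fs = fs, duration_s = duration_s, n_channels = 1,
                          events = evs), seed = seed)
  list(sim = sim, t_ons = t_ons)
}

# Two well-separated unit populations used for classifier recovery.
two_pop_spec <- function(n_per_class = 20L, duration_s = 60) {
  spike_pop_spec(classes = tibble::tibble(
    label = c("FS", "RS"),
    rate_hz = c(20, 2),
    trough_to_peak_ms = c(0.35, 0.8),
    half_width_ms = c(0.2, 0.5),
    peak_valley_ratio = c(0.35, 0.55),
    amplitude_sd = c(8, 8),
    n_units = c(n_per_class, n_per_class)),
    duration_s = duration_s)
}

# Direct, independently coded evaluation of the modulation index used as
# the oracle against the vectorized implementation: an explicit loop over
# the defining sum.
min_oracle <- function(phase, amplitude) {
  n <- length(phase)
  acc_re <- 0
  acc_im <- 0
  for (t in seq_len(n)) {
    acc_re <- acc_re + amplitude[t] * cos(phase[t])
    acc_im <- acc_im + amplitude[t] * sin(phase[t])
  }
  sqrt((acc_re / n)^2 + (acc_im / n)^2)
}
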