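test_that("gen_lfp is deterministic and honors its construction contract", {
  spec <- lfp_spec(duration_s = 10)
  a <- gen_lfp(spec, seed = 42)
  b <- gen_lfp(spec, seed = 42)
  expect_identical(a$signal$data, b$signal$data)
  c <- gen_lfp(spec, seed = 43)
  expect_false(identical(a$signal$data, c$signal$data))

  # noiseless, uncoupled: exactly two spectral peaks
  clean <- gen_lfp(lfp_spec(duration_s = 30, coupling_depth = 0,
                            noise_sd = 0, n_channels = 1), seed = 1)
  p <- welch_psd(clean$signal, n_freq_values = 1024)
  pw <- p$table$ch1
  peaks <- p$table$freq_hz[pw > 0.01 * max(pw)]
  expect_true(all(abs(peaks - 6) < 1 | abs(peaks - 40) < 1))

  # m = 1, phi = 0: gamma envelope maximal at theta phase 0
  full <- gen_lfp(lfp_spec(duration_s = 10, coupling_depth = 1,
                           coupling_phase = 0, noise_sd = 0,
                           n_channels = 1), seed = 1)
  s <- extract_pac_series(full$signal, band_presets()$theta_wide,
                          band_presets()$gamma)
  tab <- s$table
  peak_phase <- tab$phase[which.max(tab$amplitude)]
  expect_lt(abs(peak_phase), 0.2)
})

test_that("gen_lfp validates event placement", {
  expect_error(lfp_spec(duration_s = 10, events = list(
    event_spec("ripple", 9, 2, 160, 5, 1))), "beyond")
  expect_error(lfp_spec(duration_s = 10, n_channels = 2, events = list(
    event_spec("ripple", 1, 1, 160, 5, channels = 5))), "channel index")
  expect_error(event_spec("ripple", 1, 1, carrier_hz = 300, 5, 1),
               "band")
  expect_error(event_spec("fast_ripple", 1, 1, carrier_hz = 150, 5, 1),
               "band")
})

test_that("ground truth is complete: every injected event is reported once", {
  evs <- list(event_spec("ripple", 5, 0.05, 160, 5, 1),
              event_spec("fast_ripple", 10, 0.03, 300, 5, 1),
              event_spec("epileptiform", 20, 2, 150, 6, 1:6))
  sim <- gen_lfp(lfp_spec(duration_s = 30, events = evs), seed = 7)
  expect_equal(nrow(sim$truth$events), 3)
  expect_setequal(sim$truth$events$kind,
                  c("ripple", "fast_ripple", "epileptiform"))
  expect_equal(sim$truth$events$t_off,
               sim$truth$events$t_on + sim$truth$events$duration_s)
})

test_that("1/f background has the requested spectral slope", {
  sim <- gen_lfp(lfp_spec(duration_s = 120, theta_amp = 0, gamma_amp = 0,
                          noise_exponent = 1, n_channels = 1), seed = 5)
  p <- welch_psd(sim$signal, n_freq_values = 1024)
  sel <- p$table$freq_hz >= 1 & p$table$freq_hz <= 100
  fit <- stats::lm(log10(p$table$ch1[sel]) ~ log10(p$table$freq_hz[sel]))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.2)
})

test_that("gen_spikes: refractory period, rate, and template shape hold", {
  spec <- spike_pop_spec(classes = tibble::tibble(
    label = "RS", rate_hz = 10, trough_to_peak_ms = 0.8,
    half_width_ms = 0.5, peak_valley_ratio = 0.5, amplitude_sd = 8,
    n_units = 1L), refractory_ms = 1.5, duration_s = 100)
  sim <- gen_spikes(spec, seed = 2)
  ts <- sim$truth$timestamps[[1]]
  # Poisson-with-dead-time tolerance around the nominal count
  expect_lt(abs(length(ts) - 1000), 3 * sqrt(1000))
  expect_true(all(diff(ts) >= 1.5e-3))

  # same spec + seed reproduces the trace
  sim2 <- gen_spikes(spec, seed = 2)
  expect_identical(sim$signal$data, sim2$signal$data)

  # clean template trough-to-peak within one sample at 40 kHz
  u <- gen_spike_units(spike_pop_spec(classes = tibble::tibble(
    label = "RS", rate_hz = 10, trough_to_peak_ms = 0.8,
    half_width_ms = 0.5, peak_valley_ratio = 0.5, amplitude_sd = 1000,
    n_units = 1L), duration_s = 30),
    seed = 1, unit_jitter = 0)$units[[1]]
  f <- waveform_features(u)
  expect_lt(abs(f$trough_to_peak_ms - 0.8), 0.025 + 1e-9)
  expect_lt(abs(f$width_at_half_height_ms - 0.5), 0.025 + 1e-9)
  expect_equal(f$peak_valley_ratio, 0.5, tolerance = 1e-3)
})

test_that("unrealizable spike rates are rejected", {
  expect_error(spike_pop_spec(classes = tibble::tibble(
    label = "X", rate_hz = 800, trough_to_peak_ms = 0.5,
    half_width_ms = 0.3, peak_valley_ratio = 0.4, amplitude_sd = 8,
    n_units = 1L), refractory_ms = 1.5), "unrealizable")
})

test_that("gen_photometry builds the stated channel structure", {
  # no transients, motion, bleach, or noise: both channels constant
  flat <- gen_photometry(photo_spec(duration_s = 200), seed = 1)$recording
  expect_equal(stats::sd(flat$f470), 0)
  expect_equal(stats::sd(flat$f410), 0)

  # single transient of 0.1 F0 peaks at 0.1 dF/F on the clean 470 trace
  g <- gen_photometry(photo_spec(
    duration_s = 400,
    transients = tibble::tibble(t_s = 200.5, amplitude = 0.1,
                                rise_s = 0.2, decay_s = 1),
    event_tags = 200), seed = 1)
  d <- dff(g$recording, "470")
  expect_equal(max(d$dff), 0.1, tolerance = 0.02)

  # shared motion, no transients: the two dF/F traces agree up to scale
  gm <- gen_photometry(photo_spec(duration_s = 400, motion_amp = 0.03,
                                  event_tags = 200), seed = 3)
  d470 <- dff(gm$recording, "470")$dff
  d410 <- dff(gm$recording, "410")$dff
  expect_gt(stats::cor(d470, d410), 0.999)

  expect_error(photo_spec(event_tags = 60), "120 s")
  expect_error(photo_spec(f0_470 = -1), "positive")
})
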