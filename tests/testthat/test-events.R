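burst_on_channels <- function(channels, duration_s = 2, seed = 3) {
  gen_lfp(lfp_spec(duration_s = 60, events = list(
    event_spec("epileptiform", 20, duration_s, 150, 6,
               channels = channels))), seed = seed)$signal
}

test_that("epileptiform criteria are conjunctive on the canonical fixtures", {
  # valid burst: 2 s, 150 Hz, 6 SD, 6 contiguous channels -> one event
  ev <- detect_epileptiform(burst_on_channels(1:6))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 2, tolerance = 0.1)
  expect_gte(ev$n_channels_contig, 5)
  expect_gt(ev$intra_freq_hz, 100)

  # duration criterion: a 5 s burst is rejected
  expect_equal(nrow(detect_epileptiform(burst_on_channels(1:6,
                                                          duration_s = 5))),
               0)

  # contiguity criterion: 3 channels are rejected
  expect_equal(nrow(detect_epileptiform(burst_on_channels(1:3))), 0)

  # 4 non-contiguous channels are rejected even though the count is >= 4
  # under the inclusive reading
  ev4 <- detect_epileptiform(burst_on_channels(c(1, 3, 5, 7)),
                             min_channels_contig = 4)
  expect_equal(nrow(ev4), 0)
})

test_that("relaxing any epileptiform criterion can only grow the result", {
  sig <- burst_on_channels(1:6, duration_s = 5)   # fails duration
  strict <- detect_epileptiform(sig)
  relaxed_dur <- detect_epileptiform(sig, max_duration_s = 10)
  expect_gte(nrow(relaxed_dur), nrow(strict))

  sig3 <- burst_on_channels(1:3)                  # fails contiguity
  relaxed_ch <- detect_epileptiform(sig3, min_channels_contig = 3)
  expect_gte(nrow(relaxed_ch), nrow(detect_epileptiform(sig3)))
})

test_that("raising the epileptiform threshold never increases counts", {
  sig <- burst_on_channels(1:6)
  counts <- vapply(c(2, 4, 6, 10, 20),
                   function(k) nrow(detect_epileptiform(sig, sd_mult = k)),
                   1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("detector requires geometry and enough channels", {
  sig <- gen_lfp(lfp_spec(duration_s = 10, n_channels = 2), seed = 1)$signal
  expect_error(detect_epileptiform(sig), "channels")
})

test_that("ripple detector recovers injected events with accurate stats", {
  amp <- calibrate_band_amp(band_presets()$ripple, k = 5)
  mk <- make_burst_sim("ripple", 160, 50, n_ev = 20, amp_mult = amp,
                       seed = 1)
  det <- detect_ripples(mk$sim$signal)
  matched <- vapply(mk$t_ons, function(t0) min(abs(det$t_on - t0)), 1)
  expect_gte(sum(matched <= 0.025) / 20, 0.9)
  expect_equal(mean(det$intra_freq_hz), 160, tolerance = 5 / 160)

  # doubling amplitude doubles mean peak amplitude, count stays equal
  mk2 <- make_burst_sim("ripple", 160, 50, n_ev = 20, amp_mult = 2 * amp,
                        seed = 1)
  det2 <- detect_ripples(mk2$sim$signal)
  expect_equal(nrow(det2), nrow(det), tolerance = 0.1)
  ratio <- mean(det2$peak_amplitude) / mean(det$peak_amplitude)
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("raising the envelope threshold never increases band events", {
  amp <- calibrate_band_amp(band_presets()$ripple, k = 5)
  sig <- make_burst_sim("ripple", 160, 50, n_ev = 10, amp_mult = amp,
                        seed = 4)$sim$signal
  counts <- vapply(c(2, 3, 4, 6, 10), function(k) {
    nrow(detect_band_events(sig, band_presets()$ripple,
                            envelope_sd_mult = k,
                            boundary_sd_mult = min(k, 2)))
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("false-positive rate on pure noise stays within the calibrated bound", {
  # measured on seeded noise-only runs: ripple-band ~3/min, fast-ripple ~0
  rates <- vapply(1:5, function(s) {
    noise <- gen_lfp(lfp_spec(duration_s = 60, n_channels = 1,
                              theta_amp = 0, gamma_amp = 0),
                     seed = 900 + s)$signal
    nrow(detect_ripples(noise))
  }, 1L)
  expect_lte(mean(rates), 5)
})

test_that("sharp-wave-ripple promotion relabels only >200 Hz events", {
  ev <- tibble::tibble(kind = c("ripple", "ripple", "fast_ripple"),
                       t_on = c(1, 2, 3), t_off = c(1.1, 2.1, 3.1),
                       duration_s = 0.1, channels = list("ch1"),
                       n_channels_contig = 1L, peak_amplitude = 1,
                       intra_freq_hz = c(160, 250, 300))
  out <- promote_swr_events(ev)
  expect_equal(out$kind, c("ripple", "epileptiform", "epileptiform"))
})

test_that("ripple epochs overlapping epileptiform discharges are excluded", {
  rip <- tibble::tibble(t_on = c(1, 5, 9), t_off = c(1.1, 5.1, 9.1))
  epi <- tibble::tibble(t_on = 4.9, t_off = 5.5)
  kept <- exclude_overlapping(rip, epi)
  expect_equal(kept$t_on, c(1, 9))
  expect_equal(nrow(exclude_overlapping(rip, epi[0, ])), 3)
})

test_that("event summaries report rates and means per the conventions", {
  ev <- tibble::tibble(kind = "epileptiform",
                       t_on = seq(100, 3400, length.out = 12),
                       t_off = seq(100, 3400, length.out = 12) + 2,
                       duration_s = c(1, 2, 3, rep(2, 9)),
                       channels = list("ch1"), n_channels_contig = 5L,
                       peak_amplitude = 10, intra_freq_hz = 150)
  s <- summarize_events(ev, recording_duration_s = 3600)
  expect_equal(s$overall$event_rate_per_min, 0.2)
  expect_equal(s$overall$mean_duration_s, mean(c(1, 2, 3, rep(2, 9))))
  expect_equal(nrow(s$per_segment), 12)
  expect_equal(sum(s$per_segment$n_events), 12)

  s0 <- summarize_events(empty_events(), 600)
  expect_equal(s0$overall$n_events, 0)
  expect_equal(s0$overall$event_rate_per_min, 0)
  expect_true(is.na(s0$overall$mean_duration_s))

  # short trailing segment is rate-normalized by its true duration
  ev1 <- ev[1, ]
  ev1$t_on <- 610; ev1$t_off <- 612
  s2 <- summarize_events(ev1, recording_duration_s = 660)
  expect_equal(s2$per_segment$duration_s, c(300, 300, 60))
  expect_equal(s2$per_segment$event_rate_per_min[3], 1)
})
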