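test_that("spike detection recovers high-SNR ground-truth spikes", {
  spec <- spike_pop_spec(classes = tibble::tibble(
    label = "RS", rate_hz = 8, trough_to_peak_ms = 0.8,
    half_width_ms = 0.5, peak_valley_ratio = 0.5, amplitude_sd = 8,
    n_units = 1L), duration_s = 20)
  hits <- vapply(1:3, function(s) {
    sim <- gen_spikes(spec, seed = s)
    det <- detect_spikes(sim$signal)
    ts_true <- sim$truth$timestamps[[1]]
    ts_det <- det$candidates$time_s
    mean(vapply(ts_true, function(t) any(abs(ts_det - t) < 1e-3), TRUE))
  }, 1)
  expect_gte(mean(hits), 0.99)
})

test_that("noise-only detection rate matches the Gaussian crossing rate", {
  # white noise at 3 SD: crossings occur at rate ~ fs * p * (1 - p) with
  # p = pnorm(-3); detections are further thinned by the 1 ms dead time
  fs <- 40000
  set.seed(55)
  x <- continuous_signal(matrix(rnorm(fs * 5), ncol = 1), fs = fs)
  det <- detect_spikes(x)
  rate <- nrow(det$candidates) / 5
  p <- stats::pnorm(-3)
  analytic <- fs * p * (1 - p)          # crossing rate before dead time
  expect_lt(rate, analytic)             # dead time can only reduce it
  expect_gt(rate, 0.3 * analytic)       # same order of magnitude
  # zero signal: nothing at all
  z <- continuous_signal(matrix(0, fs, 1), fs = fs)
  expect_equal(nrow(detect_spikes(z)$candidates), 0)
})

test_that("refractory QC triggers exactly at the tolerance boundary", {
  # all ISIs comfortable: included
  u <- qc_unit(spike_unit(seq(0, 1, by = 0.0015)))
  expect_equal(u$qc$refractory_violation_frac, 0)
  expect_true(u$qc$included)

  # 5% of ISIs at 0.5 ms: excluded
  ts <- cumsum(c(rep(0.01, 190), rep(0.0005, 10)))
  u2 <- qc_unit(spike_unit(sort(ts)))
  expect_gt(u2$qc$refractory_violation_frac, 0.005)
  expect_false(u2$qc$included)

  # exactly at the 0.5% tolerance: included (boundary is inclusive)
  ts3 <- cumsum(c(rep(0.01, 200), 0.0005))  # 1 violation in 200 ISIs
  u3 <- qc_unit(spike_unit(ts3))
  expect_equal(u3$qc$refractory_violation_frac, 0.005)
  expect_true(u3$qc$included)

  # one more violation tips it over
  ts4 <- cumsum(c(rep(0.01, 199), 0.0005, 0.0005))
  expect_false(qc_unit(spike_unit(ts4))$qc$included)

  # < 2 spikes: excluded with reason
  u5 <- qc_unit(spike_unit(0.5))
  expect_false(u5$qc$included)
})

test_that("cross-channel coincidences are flagged above the channel count", {
  fs <- 40000
  set.seed(66)
  mat <- matrix(rnorm(fs * 2 * 8, sd = 1), ncol = 8)
  # one simultaneous transient on all 8 channels
  k <- fs  # at t = 1 s
  mat[k:(k + 10), ] <- mat[k:(k + 10), ] - 20
  x <- continuous_signal(mat, fs = fs)
  det <- flag_cross_channel_artifacts(detect_spikes(x, sd_mult = 5))
  flagged <- det$candidates[det$candidates$artifact_flag, ]
  expect_equal(length(unique(flagged$channel)), 8)
  expect_true(all(abs(flagged$time_s - 1) < 0.001))

  # coincidence on only 3 channels stays unflagged at min_channels 6
  mat2 <- matrix(rnorm(fs * 2 * 8, sd = 1), ncol = 8)
  mat2[k:(k + 10), 1:3] <- mat2[k:(k + 10), 1:3] - 20
  det2 <- flag_cross_channel_artifacts(
    detect_spikes(continuous_signal(mat2, fs = fs), sd_mult = 5))
  near <- abs(det2$candidates$time_s - 1) < 0.001
  expect_false(any(det2$candidates$artifact_flag[near]))

  # single channel: warning, no-op
  one <- detect_spikes(continuous_signal(matrix(rnorm(fs), ncol = 1) - 0,
                                         fs = fs), sd_mult = 3)
  expect_warning(flag_cross_channel_artifacts(one), "single-channel")
})

test_that("waveform features scale and ratio correctly", {
  # amplitude far above noise: the averaged waveform is template-clean
  u <- gen_spike_units(spike_pop_spec(classes = tibble::tibble(
    label = "RS", rate_hz = 10, trough_to_peak_ms = 0.8,
    half_width_ms = 0.4, peak_valley_ratio = 0.4, amplitude_sd = 1000,
    n_units = 1L), duration_s = 20),
    seed = 2, unit_jitter = 0)$units[[1]]
  f <- waveform_features(u)
  expect_equal(f$peak_valley_ratio, 0.4, tolerance = 1e-3)

  # scaling the waveform x2: ratio unchanged, slope doubled
  u2 <- u
  u2$waveforms <- 2 * u$waveforms
  f2 <- waveform_features(u2)
  expect_equal(f2$peak_valley_ratio, f$peak_valley_ratio, tolerance = 1e-9)
  expect_equal(f2$trough_peak_slope, 2 * f$trough_peak_slope,
               tolerance = 1e-9)

  # symmetric biphasic with depth 100, peak 40: ratio 0.4 exactly
  w <- c(rep(0, 10), -100, rep(0, 9), 40, rep(0, 10))
  u3 <- spike_unit(c(0.1), matrix(w, nrow = 1), fs = 40000,
                   recording_duration_s = 1)
  expect_equal(waveform_features(u3)$peak_valley_ratio, 0.4)

  # monophasic (no post-trough positivity): features absent
  wneg <- -exp(-((seq(-40, 40)) / 6)^2)
  u4 <- spike_unit(c(0.1), matrix(wneg, nrow = 1),
                   recording_duration_s = 1)
  expect_true(is.na(waveform_features(u4)$trough_to_peak_ms))
})

test_that("GMM classification separates the two populations and is stable", {
  g <- gen_spike_units(two_pop_spec(), seed = 11)
  units <- lapply(g$units, qc_unit)
  res <- classify_units(units, seed = 1)
  expect_gte(mean(res$label == g$truth$label), 0.95)

  # same data + same seed: identical labels
  res2 <- classify_units(units, seed = 1)
  expect_identical(res$label, res2$label)

  # all units identical: degenerate fit is flagged low-confidence
  u0 <- gen_spike_units(spike_pop_spec(classes = tibble::tibble(
    label = "RS", rate_hz = 5, trough_to_peak_ms = 0.8,
    half_width_ms = 0.5, peak_valley_ratio = 0.5, amplitude_sd = 1000,
    n_units = 8L), duration_s = 30),
    seed = 3, unit_jitter = 0)
  # force identical feature rows: same template, same duration, and a
  # common timestamp count via truncation to the shortest train
  n_min <- min(vapply(u0$units, function(u) length(u$timestamps), 1L))
  units0 <- lapply(u0$units, function(u) {
    spike_unit(u$timestamps[seq_len(n_min)],
               u$waveforms[seq_len(n_min), , drop = FALSE] * 0 +
                 matrix(colMeans(u0$units[[1]]$waveforms), n_min,
                        ncol(u$waveforms), byrow = TRUE),
               fs = u$fs, recording_duration_s = u$recording_duration_s,
               unit_id = u$unit_id)
  })
  res0 <- suppressWarnings(classify_units(lapply(units0, qc_unit),
                                          seed = 1))
  expect_true(all(res0$low_confidence))
  expect_true(all(abs(res0$confidence - 0.5) < 1e-9))
})

test_that("ISI histograms and per-segment counts conserve spikes", {
  # regular 10 Hz train: a single occupied bin at 100 ms
  u <- spike_unit(seq(0.1, 10, by = 0.1), recording_duration_s = 10)
  h <- isi_histogram(u, bin_ms = 1, max_ms = 200)
  expect_equal(sum(h$count), length(u$timestamps) - 1)
  # all mass within one bin of 100 ms (float jitter may straddle the edge)
  occupied <- h[h$count > 0, ]
  expect_true(all(occupied$bin_lo_ms >= 99 & occupied$bin_hi_ms <= 101))

  # counts conserve across segments, short tail normalized
  set.seed(77)
  ts <- sort(stats::runif(3000, 0, 1500))
  u2 <- spike_unit(ts, recording_duration_s = 1500)
  counts <- spike_counts_per_segment(u2, segment_s = 300)
  expect_equal(sum(counts$count), 3000)
  expect_equal(nrow(counts), 5)
  expect_true(all(abs(counts$count - 600) < 3 * sqrt(600)))

  expect_equal(nrow(isi_histogram(spike_unit(0.5))), 0)
})
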