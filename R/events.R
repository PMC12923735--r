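# Detection of epileptiform discharges and band-limited oscillatory events
# (ripples 140-200 Hz, fast ripples 200-500 Hz).

# Sliding RMS energy envelope; window in samples (odd), centered.
rms_envelope <- function(x, win) {
  if (win %% 2 == 0) win <- win + 1
  k <- rep(1 / win, win)
  e2 <- stats::filter(x^2, k, sides = 2)
  e2[is.na(e2)] <- 0
  sqrt(pmax(e2, 0))
}

gaussian_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  half <- ceiling(4 * sigma_samples)
  k <- stats::dnorm(-half:half, sd = sigma_samples)
  k <- k / sum(k)
  out <- stats::filter(x, k, sides = 2)
  idx <- which(is.na(out))
  out[idx] <- x[idx]  # edges: fall back to raw values
  as.numeric(out)
}

# Runs where mask is TRUE: tibble(start_idx, end_idx) (inclusive).
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start_idx = starts[keep], end_idx = ends[keep])
}

# Largest set of channels mutually connected under the geometry adjacency,
# restricted to `channels`.
largest_contiguous <- function(channels, geometry) {
  if (length(channels) == 0) return(character())
  adj <- lapply(stats::setNames(channels, channels), function(ch) {
    nb <- unlist(lapply(geometry, function(p) {
      if (p[1] == ch) p[2] else if (p[2] == ch) p[1] else NULL
    }))
    intersect(nb, channels)
  })
  seen <- character()
  best <- character()
  for (root in channels) {
    if (root %in% seen) next
    comp <- root
    frontier <- root
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), comp)
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    seen <- c(seen, comp)
    if (length(comp) > length(best)) best <- comp
  }
  best
}

# Dominant intra-event oscillation frequency from the positive local maxima
# of the band-limited trace: one oscillation cycle per peak, so the span
# between the first and last peak divided by the cycle count gives the
# period at sub-sample resolution (a plain median inter-peak interval would
# quantize to whole samples). Outlier intervals (> 2x median, i.e. missed
# cycles) are excluded from the span.
intra_event_freq <- function(trace, fs) {
  n <- length(trace)
  if (n < 3) return(NA_real_)
  pk <- which(diff(sign(diff(trace))) < 0) + 1
  pk <- pk[trace[pk] > 0]
  if (length(pk) < 2) return(NA_real_)
  iv <- diff(pk)
  med <- stats::median(iv)
  good <- iv <= 2 * med
  if (!any(good)) return(fs / med)
  fs / mean(iv[good])
}

#' Detect epileptiform discharges
#'
#' Implements conjunctive detection criteria for epileptiform activity:
#' high-frequency (> `hf_cut_hz`) signal energy rising more than `sd_mult`
#' standard deviations above its baseline, lasting at most `max_duration_s`,
#' and present on at least `min_channels_contig` channels that are
#' contiguous under the electrode geometry ("more than 4 contiguous
#' channels" read literally as >= 5; set `min_channels_contig = 4` for the
#' inclusive reading).
#'
#' Per channel, the signal is high-pass filtered at `hf_cut_hz` and a
#' short-window RMS energy envelope is thresholded at baseline mean +
#' `sd_mult` x baseline SD. Baseline statistics use the whole recording
#' with a second pass that excludes first-pass detections (`baseline =
#' "auto"`), or a user-stated interval. Supra-threshold runs overlapping in
#' time across channels are merged into one candidate event whose channel
#' set is the union; candidates failing the contiguity or duration
#' criterion are discarded.
#'
#' @param x A multi-channel [continuous_signal()] with geometry.
#' @param baseline `"auto"` or a numeric `c(start_s, end_s)` interval.
#' @param sd_mult Envelope threshold in baseline SDs (default 4).
#' @param min_channels_contig Minimum contiguous-channel count (default 5).
#' @param max_duration_s Maximum event duration, seconds (default 4).
#' @param hf_cut_hz High-pass cutoff, Hz (default 100).
#' @param energy_win_s RMS envelope window, seconds (default 0.02).
#' @param merge_gap_s Supra-threshold runs on one channel closer than this
#'   are merged before cross-channel grouping (default 0.05).
#' @return A tibble of events: `kind`, `t_on`, `t_off`, `duration_s`,
#'   `channels` (list-column), `n_channels_contig`, `peak_amplitude`,
#'   `intra_freq_hz`.
#' @export
detect_epileptiform <- function(x, baseline = "auto", sd_mult = 4,
                                min_channels_contig = 5, max_duration_s = 4,
                                hf_cut_hz = 100, energy_win_s = 0.02,
                                merge_gap_s = 0.05) {
  stopifnot(inherits(x, "continuous_signal"))
  if (length(x$geometry) == 0 && ncol(x$data) > 1) {
    stop("signal has no channel geometry; contiguity cannot be evaluated",
         call. = FALSE)
  }
  if (ncol(x$data) < min_channels_contig) {
    stop(sprintf("need at least %d channels with geometry",
                 min_channels_contig), call. = FALSE)
  }
  hp <- bandpass(x, band_def("hf", hf_cut_hz, min(x$fs / 2 - 1, 4 * hf_cut_hz)),
                 type = "high")
  win <- round(energy_win_s * x$fs)
  env <- apply(hp$data, 2, rms_envelope, win = win)

  runs_all <- purrr::map_dfr(seq_len(ncol(env)), function(ch) {
    e <- env[, ch]
    stats <- envelope_baseline(e, baseline, sd_mult, x$fs)
    thr <- stats$mean + sd_mult * stats$sd
    runs <- mask_runs(e > thr)
    if (nrow(runs) == 0) return(runs)
    runs <- merge_close_runs(runs, round(merge_gap_s * x$fs))
    runs$channel <- x$channel_ids[ch]
    runs
  })
  if (nrow(runs_all) == 0) return(empty_events())

  groups <- group_overlapping_runs(runs_all)
  events <- purrr::map_dfr(groups, function(g) {
    chans <- unique(g$channel)
    contig <- largest_contiguous(chans, x$geometry)
    i0 <- min(g$start_idx); i1 <- max(g$end_idx)
    dur <- (i1 - i0 + 1) / x$fs
    if (length(contig) < min_channels_contig || dur > max_duration_s) {
      return(empty_events())
    }
    sub_env <- env[i0:i1, match(chans, x$channel_ids), drop = FALSE]
    best_ch <- chans[which.max(apply(sub_env, 2, max))]
    tr <- hp$data[i0:i1, match(best_ch, x$channel_ids)]
    tibble::tibble(
      kind = "epileptiform",
      t_on = x$t0 + (i0 - 1) / x$fs,
      t_off = x$t0 + i1 / x$fs,
      duration_s = dur,
      channels = list(chans),
      n_channels_contig = length(contig),
      peak_amplitude = max(sub_env),
      intra_freq_hz = intra_event_freq(tr, x$fs)
    )
  })
  dplyr::arrange(events, .data$t_on)
}

empty_events <- function() {
  tibble::tibble(kind = character(), t_on = numeric(), t_off = numeric(),
                 duration_s = numeric(), channels = list(),
                 n_channels_contig = integer(), peak_amplitude = numeric(),
                 intra_freq_hz = numeric())
}

# Baseline mean/SD of an envelope, two-pass when auto: the first pass
# thresholds, the second recomputes statistics excluding detected samples.
envelope_baseline <- function(e, baseline, sd_mult, fs) {
  if (is.numeric(baseline) && length(baseline) == 2) {
    idx <- seq(max(1, round(baseline[1] * fs) + 1),
               min(length(e), round(baseline[2] * fs)))
    base <- e[idx]
    thr <- mean(base) + sd_mult * stats::sd(base)
    if (any(base > thr)) {
      warning("baseline interval contains supra-threshold activity; ",
              "recomputing baseline excluding it")
      base <- base[base <= thr]
    }
    return(list(mean = mean(base), sd = stats::sd(base)))
  }
  m1 <- mean(e); s1 <- stats::sd(e)
  keep <- e <= m1 + sd_mult * s1
  list(mean = mean(e[keep]), sd = stats::sd(e[keep]))
}

merge_close_runs <- function(runs, max_gap) {
  if (nrow(runs) <= 1) return(runs)
  runs <- runs[order(runs$start_idx), ]
  out_s <- runs$start_idx[1]; out_e <- runs$end_idx[1]
  res_s <- c(); res_e <- c()
  for (i in 2:nrow(runs)) {
    if (runs$start_idx[i] - out_e <= max_gap) {
      out_e <- max(out_e, runs$end_idx[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- runs$start_idx[i]; out_e <- runs$end_idx[i]
    }
  }
  tibble::tibble(start_idx = c(res_s, out_s), end_idx = c(res_e, out_e))
}

# Cluster per-channel runs whose index intervals overlap in time.
group_overlapping_runs <- function(runs) {
  runs <- runs[order(runs$start_idx), ]
  groups <- list()
  cur <- runs[1, ]
  cur_end <- runs$end_idx[1]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start_idx[i] <= cur_end) {
      cur <- dplyr::bind_rows(cur, runs[i, ])
      cur_end <- max(cur_end, runs$end_idx[i])
    } else {
      groups[[length(groups) + 1]] <- cur
      cur <- runs[i, ]
      cur_end <- runs$end_idx[i]
    }
  }
  groups[[length(groups) + 1]] <- cur
  groups
}

#' Detect band-limited oscillatory events (ripples, fast ripples)
#'
#' Band-pass filters one channel, takes the analytic-signal amplitude
#' envelope, smooths it with a Gaussian kernel (sigma 4 ms), and marks
#' intervals where the envelope exceeds its mean by `envelope_sd_mult`
#' standard deviations for at least `min_duration_ms`; intervals closer
#' than `merge_gap_ms` are merged. Per event the peak envelope amplitude
#' and the dominant intra-event oscillation frequency (reciprocal median
#' inter-peak interval of the band-limited trace) are reported.
#'
#' `detect_ripples()` and `detect_fast_ripples()` apply the presets
#' 140-200 Hz / 20 ms and 200-500 Hz / 10 ms respectively.
#'
#' @param x A [continuous_signal()] with `fs >= 2 * band$f_hi`.
#' @param band A [band_def()].
#' @param envelope_sd_mult Core envelope threshold in SDs above the mean
#'   (default 3); an event must exceed this.
#' @param boundary_sd_mult Lower boundary threshold in SDs (default 2):
#'   event edges extend outward from each core crossing to where the
#'   envelope falls back below this level (dual-threshold convention, which
#'   keeps brief in-event envelope dips from splitting an event).
#' @param min_duration_ms Minimum event duration, ms.
#' @param min_core_ms Minimum time the envelope must stay above the core
#'   threshold (default half of `min_duration_ms`); transient single-sample
#'   noise exceedances are thereby not promoted to events.
#' @param merge_gap_ms Events separated by less than this are merged, ms.
#' @param channel Channel id or index.
#' @param smooth_sigma_ms Gaussian smoothing sigma for the envelope, ms.
#' @param kind Event label stored in the result.
#' @return A tibble of events with the same columns as
#'   [detect_epileptiform()].
#' @export
detect_band_events <- function(x, band, envelope_sd_mult = 3,
                               boundary_sd_mult = 2,
                               min_duration_ms = 20,
                               min_core_ms = min_duration_ms / 2,
                               merge_gap_ms = 10,
                               channel = 1, smooth_sigma_ms = 4,
                               kind = band$name) {
  stopifnot(inherits(x, "continuous_signal"))
  check_band_nyquist(band, x$fs)
  if (boundary_sd_mult > envelope_sd_mult) {
    stop("`boundary_sd_mult` must not exceed `envelope_sd_mult`",
         call. = FALSE)
  }
  ch <- resolve_channel(x, channel)
  xs <- continuous_signal(x$data[, ch], fs = x$fs, t0 = x$t0,
                          units = x$units)
  bp <- bandpass(xs, band)$data[, 1]
  env_raw <- Mod(analytic_signal(bp))
  env <- gaussian_smooth(env_raw, smooth_sigma_ms / 1000 * x$fs)
  # thresholds refer to the unsmoothed envelope's statistics; smoothing
  # only stabilizes run boundaries
  mu <- mean(env_raw); s <- stats::sd(env_raw)
  thr_core <- mu + envelope_sd_mult * s
  runs <- mask_runs(env > thr_core)
  runs <- runs[(runs$end_idx - runs$start_idx + 1) >=
                 round(min_core_ms / 1000 * x$fs), ]
  if (nrow(runs) == 0) return(empty_events())
  # extend each core run outward to the lower boundary crossing
  bound_runs <- mask_runs(env > mu + boundary_sd_mult * s)
  runs <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    host <- which(bound_runs$start_idx <= runs$start_idx[i] &
                    bound_runs$end_idx >= runs$end_idx[i])
    if (length(host)) bound_runs[host[1], ] else runs[i, ]
  })
  runs <- unique(runs)
  runs <- merge_close_runs(runs, round(merge_gap_ms / 1000 * x$fs))
  runs <- runs[(runs$end_idx - runs$start_idx + 1) >=
                 round(min_duration_ms / 1000 * x$fs), ]
  if (nrow(runs) == 0) return(empty_events())
  purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    i0 <- runs$start_idx[i]; i1 <- runs$end_idx[i]
    tibble::tibble(
      kind = kind,
      t_on = x$t0 + (i0 - 1) / x$fs,
      t_off = x$t0 + i1 / x$fs,
      duration_s = (i1 - i0 + 1) / x$fs,
      channels = list(x$channel_ids[ch]),
      n_channels_contig = 1L,
      peak_amplitude = max(env[i0:i1]),
      intra_freq_hz = intra_event_freq(bp[i0:i1], x$fs)
    )
  })
}

#' @rdname detect_band_events
#' @param ... Passed on to [detect_band_events()].
#' @export
detect_ripples <- function(x, channel = 1, envelope_sd_mult = 3, ...) {
  detect_band_events(x, band_presets()$ripple,
                     envelope_sd_mult = envelope_sd_mult,
                     min_duration_ms = 20, channel = channel,
                     kind = "ripple", ...)
}

#' @rdname detect_band_events
#' @export
detect_fast_ripples <- function(x, channel = 1, envelope_sd_mult = 3, ...) {
  detect_band_events(x, band_presets()$fast_ripple,
                     envelope_sd_mult = envelope_sd_mult,
                     min_duration_ms = 10, channel = channel,
                     kind = "fast_ripple", ...)
}

#' Relabel sharp-wave-ripple-type events as epileptiform
#'
#' During freely-moving epochs, detected high-frequency oscillatory events
#' whose dominant intra-event frequency exceeds 200 Hz are considered
#' epileptiform and relabelled accordingly.
#'
#' @param events An event tibble from a detector.
#' @param freq_cut_hz Dominant-frequency cutoff (default 200).
#' @return The event tibble with `kind` updated.
#' @export
promote_swr_events <- function(events, freq_cut_hz = 200) {
  hit <- !is.na(events$intra_freq_hz) & events$intra_freq_hz > freq_cut_hz
  events$kind[hit] <- "epileptiform"
  events
}

#' Drop events overlapping a reference set
#'
#' Used to exclude epochs containing epileptiform discharges from
#' physiological ripple summaries.
#'
#' @param events,reference Event tibbles (with `t_on`, `t_off`).
#' @return `events` without rows overlapping any `reference` interval.
#' @export
exclude_overlapping <- function(events, reference) {
  if (nrow(events) == 0 || nrow(reference) == 0) return(events)
  keep <- vapply(seq_len(nrow(events)), function(i) {
    !any(events$t_on[i] < reference$t_off & events$t_off[i] > reference$t_on)
  }, TRUE)
  events[keep, ]
}

#' Summarize detected events
#'
#' Overall and per-segment event rates (events per minute, normalized by
#' actual segment durations, including a trailing short segment) and mean
#' event characteristics. Means are reported as `NA` when there are no
#' events.
#'
#' @param events An event tibble.
#' @param recording_duration_s Total recording duration, seconds.
#' @param segment_s Segment length for per-segment counts (default 300).
#' @return A list with `overall` (one-row tibble: `n_events`,
#'   `event_rate_per_min`, `mean_intra_freq_hz`, `mean_peak_amplitude`,
#'   `mean_duration_s`) and `per_segment` (tibble with `index`,
#'   `duration_s`, `n_events`, `event_rate_per_min`).
#' @export
summarize_events <- function(events, recording_duration_s,
                             segment_s = 300) {
  if (recording_duration_s <= 0) stop("duration must be positive",
                                      call. = FALSE)
  n <- nrow(events)
  overall <- tibble::tibble(
    n_events = n,
    event_rate_per_min = n / (recording_duration_s / 60),
    mean_intra_freq_hz = if (n) mean(events$intra_freq_hz, na.rm = TRUE)
                         else NA_real_,
    mean_peak_amplitude = if (n) mean(events$peak_amplitude) else NA_real_,
    mean_duration_s = if (n) mean(events$duration_s) else NA_real_
  )
  n_seg <- ceiling(recording_duration_s / segment_s)
  start <- (seq_len(n_seg) - 1) * segment_s
  end <- pmin(start + segment_s, recording_duration_s)
  counts <- vapply(seq_len(n_seg), function(i) {
    if (n == 0) 0L else sum(events$t_on >= start[i] & events$t_on < end[i])
  }, 1L)
  per_segment <- tibble::tibble(
    index = seq_len(n_seg), start_s = start, end_s = end,
    duration_s = end - start, n_events = counts,
    event_rate_per_min = counts / ((end - start) / 60)
  )
  list(overall = overall, per_segment = per_segment)
}
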