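# Spike detection, unit quality control, waveform features, and
# fast-spiking / regular-spiking classification.

#' Spike unit container
#'
#' Holds the timestamps and trough-aligned waveforms of one putative
#' single unit, together with QC fields filled by [qc_unit()] and a class
#' label set by [classify_units()]. Waveform windows span -0.5 to +1.5 ms
#' around the trough.
#'
#' @param timestamps Spike times, seconds, strictly increasing.
#' @param waveforms Numeric matrix, one row per spike (may have zero rows
#'   for timestamp-only units).
#' @param fs Waveform sampling rate, Hz.
#' @param recording_duration_s Duration of the source recording, used for
#'   the firing rate.
#' @param unit_id Unit label.
#' @param channel Source channel id, if known.
#' @return A `spike_unit` object.
#' @export
spike_unit <- function(timestamps, waveforms = NULL, fs = 40000,
                       recording_duration_s = NULL, unit_id = "u1",
                       channel = NA_character_) {
  timestamps <- as.numeric(timestamps)
  if (is.unsorted(timestamps, strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (is.null(recording_duration_s)) {
    recording_duration_s <- if (length(timestamps)) max(timestamps) else 0
  }
  if (!is.null(waveforms)) {
    waveforms <- as.matrix(waveforms)
    if (nrow(waveforms) != length(timestamps)) {
      stop("one waveform row per timestamp required", call. = FALSE)
    }
  }
  structure(list(timestamps = timestamps, waveforms = waveforms, fs = fs,
                 recording_duration_s = recording_duration_s,
                 unit_id = unit_id, channel = channel,
                 qc = list(refractory_violation_frac = NA_real_,
                           artifact_flag = FALSE, included = NA),
                 label = "unclassified"),
            class = "spike_unit")
}

#' @export
print.spike_unit <- function(x, ...) {
  cat(sprintf("<spike_unit> %s: %d spikes, %.2f Hz, label %s\n",
              x$unit_id, length(x$timestamps),
              length(x$timestamps) / max(x$recording_duration_s, 1e-12),
              x$label))
  invisible(x)
}

#' Detect spikes by negative threshold crossing
#'
#' Estimates the noise SD per channel robustly (median absolute deviation
#' scaled to the Gaussian SD), marks negative-going crossings of
#' `-sd_mult` x noise SD, aligns a -0.5/+1.5 ms window on each trough, and
#' enforces a 1 ms dead time after each detection. Detections whose window
#' would exceed the recording bounds are dropped and counted.
#'
#' @param x A spike-band [continuous_signal()] (40 kHz-class).
#' @param sd_mult Detection threshold in noise SDs (default 3).
#' @param dead_time_ms Minimum separation between detections on one
#'   channel, ms.
#' @return A list with `candidates` — tibble (`time_s`, `channel`,
#'   `trough_uv`, `artifact_flag`, `waveform` list-column) — and
#'   `n_dropped` (windows out of bounds).
#' @export
detect_spikes <- function(x, sd_mult = 3, dead_time_ms = 1) {
  stopifnot(inherits(x, "continuous_signal"))
  pre <- round(0.5e-3 * x$fs)
  post <- round(1.5e-3 * x$fs)
  dead <- round(dead_time_ms / 1000 * x$fs)
  n <- nrow(x$data)
  dropped <- 0L
  cand <- purrr::map_dfr(seq_len(ncol(x$data)), function(ch) {
    v <- x$data[, ch]
    noise_sd <- stats::mad(v)  # MAD / 0.6745
    thr <- -sd_mult * noise_sd
    below <- v < thr
    if (!any(below)) return(NULL)
    runs <- mask_runs(below)
    troughs <- vapply(seq_len(nrow(runs)), function(i) {
      idx <- runs$start_idx[i]:runs$end_idx[i]
      idx[which.min(v[idx])]
    }, 1L)
    # dead time: accept in order, skip troughs within `dead` samples
    acc <- integer()
    last <- -Inf
    for (tr in troughs) {
      if (tr - last >= dead) { acc <- c(acc, tr); last <- tr }
    }
    ok <- acc - pre >= 1 & acc + post <= n
    dropped <<- dropped + sum(!ok)
    acc <- acc[ok]
    if (!length(acc)) return(NULL)
    wf <- t(vapply(acc, function(tr) v[(tr - pre):(tr + post)],
                   numeric(pre + post + 1)))
    tibble::tibble(time_s = x$t0 + (acc - 1) / x$fs,
                   channel = x$channel_ids[ch],
                   trough_uv = v[acc],
                   artifact_flag = FALSE,
                   waveform = lapply(seq_len(nrow(wf)), function(i) wf[i, ]))
  })
  list(candidates = cand, n_dropped = dropped, fs = x$fs,
       recording_duration_s = signal_duration(x))
}

#' Flag cross-channel coincidence artifacts
#'
#' Detections that occur nearly simultaneously on most channels are
#' electrical artifacts, not spikes. Any detection coincident (within
#' `coincidence_window_ms`) with detections on at least `min_channels`
#' distinct channels (itself included) is flagged.
#'
#' @param detections The list returned by [detect_spikes()].
#' @param coincidence_window_ms Coincidence window, ms (default 0.5).
#' @param min_channels Minimum coincident channel count to flag
#'   (default 6).
#' @return `detections` with `artifact_flag` set on flagged rows.
#' @export
flag_cross_channel_artifacts <- function(detections,
                                         coincidence_window_ms = 0.5,
                                         min_channels = 6) {
  cand <- detections$candidates
  if (is.null(cand) || nrow(cand) == 0) return(detections)
  if (length(unique(cand$channel)) < 2) {
    warning("single-channel detections: cross-channel artifact flagging ",
            "is a no-op")
    return(detections)
  }
  w <- coincidence_window_ms / 1000
  flag <- vapply(seq_len(nrow(cand)), function(i) {
    near <- abs(cand$time_s - cand$time_s[i]) <= w
    length(unique(cand$channel[near])) >= min_channels
  }, TRUE)
  detections$candidates$artifact_flag <- flag
  detections
}

#' Assemble per-channel spike units from detections
#'
#' Single-template-per-channel convention: all unflagged detections on one
#' channel form one candidate unit.
#'
#' @param detections The list returned by [detect_spikes()] (optionally
#'   after [flag_cross_channel_artifacts()]).
#' @return A list of [spike_unit()] objects.
#' @export
candidates_to_units <- function(detections) {
  cand <- detections$candidates
  cand <- cand[!cand$artifact_flag, ]
  chans <- unique(cand$channel)
  lapply(chans, function(ch) {
    sub <- cand[cand$channel == ch, ]
    sub <- sub[order(sub$time_s), ]
    wf <- do.call(rbind, sub$waveform)
    spike_unit(sub$time_s, wf, fs = detections$fs,
               recording_duration_s = detections$recording_duration_s,
               unit_id = paste0("unit_", ch), channel = ch)
  })
}

#' Refractory-period quality control
#'
#' A well-isolated single unit cannot fire twice within its absolute
#' refractory period; inter-spike intervals below `refractory_ms` indicate
#' contamination. The unit is retained when the fraction of violating ISIs
#' is at most `violation_tol` (boundary inclusive) and the unit is not an
#' artifact.
#'
#' @param unit A [spike_unit()] with at least 2 spikes.
#' @param refractory_ms Absolute refractory period, ms (default 1).
#' @param violation_tol Maximum tolerated violation fraction
#'   (default 0.005).
#' @return The unit with `qc$refractory_violation_frac` and `qc$included`
#'   set.
#' @export
qc_unit <- function(unit, refractory_ms = 1, violation_tol = 0.005) {
  stopifnot(inherits(unit, "spike_unit"))
  if (length(unit$timestamps) < 2) {
    unit$qc$included <- FALSE
    unit$qc$exclusion_reason <- "fewer than 2 spikes"
    return(unit)
  }
  isis_ms <- diff(unit$timestamps) * 1000
  frac <- mean(isis_ms < refractory_ms)
  unit$qc$refractory_violation_frac <- frac
  unit$qc$included <- (frac <= violation_tol) && !unit$qc$artifact_flag
  if (!unit$qc$included) {
    unit$qc$exclusion_reason <- if (unit$qc$artifact_flag) "artifact"
                                else "refractory violations"
  }
  unit
}

#' Waveform features of a spike unit
#'
#' Computed on the mean waveform: `trough_to_peak_ms` (time from the global
#' trough to the subsequent maximum), `width_at_half_height_ms` (width of
#' the trough at half its depth, linearly interpolated between samples),
#' `peak_valley_ratio` (|post-trough peak| / |trough|), and
#' `trough_peak_slope` ((peak - trough) / trough-to-peak time, units per
#' ms); plus `firing_rate_hz`. When no post-trough peak exists within the
#' window the waveform features are `NA` and the unit cannot be
#' classified.
#'
#' @param unit A [spike_unit()] with waveforms.
#' @return One-row tibble of features.
#' @export
waveform_features <- function(unit) {
  stopifnot(inherits(unit, "spike_unit"))
  rate <- length(unit$timestamps) / unit$recording_duration_s
  if (is.null(unit$waveforms) || nrow(unit$waveforms) == 0) {
    return(tibble::tibble(unit_id = unit$unit_id, firing_rate_hz = rate,
                          trough_to_peak_ms = NA_real_,
                          width_at_half_height_ms = NA_real_,
                          peak_valley_ratio = NA_real_,
                          trough_peak_slope = NA_real_))
  }
  w <- colMeans(unit$waveforms)
  dt_ms <- 1000 / unit$fs
  i_tr <- which.min(w)
  trough <- w[i_tr]
  after <- if (i_tr < length(w)) w[(i_tr + 1):length(w)] else numeric()
  if (!length(after) || max(after) <= 0) {
    return(tibble::tibble(unit_id = unit$unit_id, firing_rate_hz = rate,
                          trough_to_peak_ms = NA_real_,
                          width_at_half_height_ms = NA_real_,
                          peak_valley_ratio = NA_real_,
                          trough_peak_slope = NA_real_))
  }
  i_pk <- i_tr + which.max(after)
  peak <- w[i_pk]
  t2p <- (i_pk - i_tr) * dt_ms
  half <- trough / 2  # half depth (negative)
  left <- cross_time(w, i_tr, -1, half)
  right <- cross_time(w, i_tr, +1, half)
  width <- (right - left) * dt_ms
  tibble::tibble(
    unit_id = unit$unit_id,
    firing_rate_hz = rate,
    trough_to_peak_ms = t2p,
    width_at_half_height_ms = width,
    peak_valley_ratio = abs(peak) / abs(trough),
    trough_peak_slope = (peak - trough) / t2p
  )
}

# Fractional sample index where w crosses `level` moving from i0 in
# direction dir (+1/-1); linear interpolation between samples.
cross_time <- function(w, i0, dir, level) {
  i <- i0
  while (i + dir >= 1 && i + dir <= length(w) && w[i + dir] < level) {
    i <- i + dir
  }
  j <- i + dir
  if (j < 1 || j > length(w)) return(i)
  # w[i] < level <= w[j]
  i + dir * (level - w[i]) / (w[j] - w[i])
}

#' Classify units as fast-spiking or regular-spiking
#'
#' Fits a 2-component full-covariance Gaussian mixture to standardized
#' (log firing rate, peak-valley ratio, width at half height). The
#' component with the shorter mean spike width is labelled `FS`
#' (fast-spiking, putative PV+ interneurons), the other `RS`
#' (regular-spiking, putative pyramidal cells). The fit uses a
#' deterministic model-based hierarchical initialization, so the result is
#' reproducible; `seed` is consumed for interface stability. If the full
#' covariance model is singular, a diagonal model is fitted with a
#' warning. Units whose posterior class probability is below 0.55 are
#' flagged low-confidence.
#'
#' @param units A list of [spike_unit()]s (only `qc$included` units enter
#'   the fit; pass units through [qc_unit()] first, or all units are
#'   used).
#' @param seed Integer seed.
#' @return A tibble: `unit_id`, features, `label` (`FS`/`RS`/
#'   `unclassified`), `confidence` (posterior probability),
#'   `low_confidence`.
#' @importFrom mclust Mclust mclustBIC
#' @export
classify_units <- function(units, seed = 1) {
  feats <- purrr::map_dfr(units, waveform_features)
  included <- vapply(units, function(u) {
    isTRUE(u$qc$included) || is.na(u$qc$included)
  }, TRUE)
  usable <- included & stats::complete.cases(
    feats[, c("firing_rate_hz", "peak_valley_ratio",
              "width_at_half_height_ms")])
  feats$label <- "unclassified"
  feats$confidence <- NA_real_
  feats$low_confidence <- NA
  if (sum(usable) < 2) return(feats)
  X <- scale(cbind(log(feats$firing_rate_hz[usable]),
                   feats$peak_valley_ratio[usable],
                   feats$width_at_half_height_ms[usable]))
  X[!is.finite(X)] <- 0  # zero-variance column => all-equal feature
  if (max(stats::dist(X)) < 1e-8) {
    # indistinguishable units: both mixture components coincide, so every
    # assignment is arbitrary; report one class at responsibility 0.5
    feats$label[usable] <- "RS"
    feats$confidence[usable] <- 0.5
    feats$low_confidence[usable] <- TRUE
    return(feats)
  }
  fit <- with_local_seed(seed, {
    f <- tryCatch(
      suppressWarnings(mclust::Mclust(X, G = 2, modelNames = "VVV",
                                      verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(f)) {
      warning("full-covariance mixture singular; falling back to diagonal")
      f <- suppressWarnings(mclust::Mclust(X, G = 2, modelNames = "VVI",
                                           verbose = FALSE))
    }
    f
  })
  if (is.null(fit)) return(feats)
  cls <- fit$classification
  mean_width <- vapply(1:2, function(g) {
    mean(feats$width_at_half_height_ms[usable][cls == g])
  }, 1)
  fs_comp <- which.min(mean_width)
  feats$label[usable] <- ifelse(cls == fs_comp, "FS", "RS")
  conf <- apply(fit$z, 1, max)
  feats$confidence[usable] <- conf
  feats$low_confidence[usable] <- conf < 0.55
  feats
}

#' Inter-spike interval histogram
#'
#' @param unit A [spike_unit()] with at least 2 spikes.
#' @param bin_ms Bin width, ms.
#' @param max_ms Nominal upper edge, ms; extended in whole bins if any ISI
#'   exceeds it, so the counts always sum to `n_spikes - 1`.
#' @return A tibble with `bin_lo_ms`, `bin_hi_ms`, `count`.
#' @export
isi_histogram <- function(unit, bin_ms = 1, max_ms = 100) {
  stopifnot(inherits(unit, "spike_unit"))
  if (length(unit$timestamps) < 2) {
    return(tibble::tibble(bin_lo_ms = numeric(), bin_hi_ms = numeric(),
                          count = integer()))
  }
  isis <- diff(unit$timestamps) * 1000
  top <- bin_ms * ceiling(max(max_ms, max(isis) + 1e-9) / bin_ms)
  edges <- seq(0, top, by = bin_ms)
  counts <- as.integer(table(cut(isis, edges, right = FALSE,
                                 include.lowest = TRUE)))
  tibble::tibble(bin_lo_ms = utils::head(edges, -1),
                 bin_hi_ms = utils::tail(edges, -1),
                 count = counts)
}

#' Spike counts per sequential segment
#'
#' Counts spikes in sequential fixed-length segments (default 5 minutes),
#' with rates normalized by true segment duration (a trailing short
#' segment is retained).
#'
#' @param unit A [spike_unit()].
#' @param segment_s Segment length, seconds.
#' @return A tibble with `index`, `start_s`, `end_s`, `duration_s`,
#'   `count`, `rate_hz`.
#' @export
spike_counts_per_segment <- function(unit, segment_s = 300) {
  stopifnot(inherits(unit, "spike_unit"))
  dur <- unit$recording_duration_s
  n_seg <- max(1L, ceiling(dur / segment_s))
  start <- (seq_len(n_seg) - 1) * segment_s
  end <- pmin(start + segment_s, dur)
  counts <- vapply(seq_len(n_seg), function(i) {
    sum(unit$timestamps >= start[i] & unit$timestamps < end[i])
  }, 1L)
  tibble::tibble(index = seq_len(n_seg), start_s = start, end_s = end,
                 duration_s = end - start, count = counts,
                 rate_hz = counts / (end - start))
}
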