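# Fiber photometry: delta-F/F with a per-tag 2-minute baseline, an
# isosbestic (410 nm) control channel, and event-aligned summaries.

#' Two-channel photometry recording container
#'
#' Paired 470 nm (calcium-sensitive) and 410 nm (isosbestic,
#' calcium-insensitive control) fluorescence traces with behavioral event
#' tags. Each tag must fall at least 120 s after the recording start so a
#' 2-minute pre-event baseline exists.
#'
#' @param f470,f410 Fluorescence traces, equal length, strictly positive.
#' @param fs Sampling rate, Hz.
#' @param event_tags Event times, seconds.
#' @param t0 Start time, seconds.
#' @return A `photometry_recording` object.
#' @export
photometry_recording <- function(f470, f410, fs, event_tags = numeric(),
                                 t0 = 0) {
  if (length(f470) != length(f410)) {
    stop("channels must have equal length", call. = FALSE)
  }
  if (any(f470 <= 0) || any(f410 <= 0)) {
    stop("fluorescence values must be positive", call. = FALSE)
  }
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (length(event_tags) && any(event_tags < t0 + 120)) {
    stop("each event tag must be at least 120 s after the recording start",
         call. = FALSE)
  }
  structure(list(f470 = as.numeric(f470), f410 = as.numeric(f410),
                 fs = fs, event_tags = sort(as.numeric(event_tags)),
                 t0 = t0),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf(
    "<photometry_recording> %d samples @ %g Hz (%.1f s), %d event tag(s)\n",
    length(x$f470), x$fs, length(x$f470) / x$fs, length(x$event_tags)))
  invisible(x)
}

photo_channel <- function(rec, channel) {
  channel <- as.character(channel)
  if (!channel %in% c("470", "410")) {
    stop('`channel` must be "470" or "410"', call. = FALSE)
  }
  if (channel == "470") rec$f470 else rec$f410
}

#' Per-tag delta-F/F
#'
#' For each event tag, the baseline `F0` is the mean of the chosen channel
#' over the 2 minutes preceding the tag (`[tag - 120 s, tag)`), and
#' `dF/F(t) = (F(t) - F0) / F0` on the event window. Tags whose baseline
#' would precede the recording start are skipped with a warning.
#'
#' @param rec A [photometry_recording()].
#' @param channel `"470"` or `"410"`.
#' @param pre_s,post_s Event window around each tag, seconds (default -2
#'   to +5 s).
#' @param baseline_s Baseline duration, seconds (default 120).
#' @return A tibble with one row per sample per usable tag: `tag_index`,
#'   `tag_s`, `rel_time_s`, `f0`, `dff`.
#' @export
dff <- function(rec, channel = "470", pre_s = 2, post_s = 5,
                baseline_s = 120) {
  stopifnot(inherits(rec, "photometry_recording"))
  f <- photo_channel(rec, channel)
  n <- length(f)
  n_skipped <- 0L
  out <- purrr::map_dfr(seq_along(rec$event_tags), function(k) {
    tag <- rec$event_tags[k]
    b0 <- round((tag - baseline_s - rec$t0) * rec$fs) + 1
    b1 <- round((tag - rec$t0) * rec$fs)
    if (b0 < 1) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    f0 <- mean(f[b0:b1])
    i0 <- round((tag - pre_s - rec$t0) * rec$fs) + 1
    i1 <- round((tag + post_s - rec$t0) * rec$fs)
    if (i1 > n) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    idx <- i0:i1
    tibble::tibble(tag_index = k, tag_s = tag,
                   rel_time_s = (idx - 1) / rec$fs + rec$t0 - tag,
                   f0 = f0, dff = (f[idx] - f0) / f0)
  })
  if (n_skipped > 0) {
    warning(sprintf("%d tag(s) skipped (incomplete baseline or window)",
                    n_skipped))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Event-aligned delta-F/F matrix, mean and SEM
#'
#' Aligns the per-tag dF/F windows of [dff()] on a common relative-time
#' grid (linear interpolation at the native sampling rate) and summarizes
#' them as a per-event matrix (heatmap), a mean curve, and a SEM curve.
#'
#' @inheritParams dff
#' @return A `dff_trace`: list with `matrix` (events x time), `rel_time_s`,
#'   `summary` (tibble: `rel_time_s`, `mean`, `sem`), `channel`,
#'   `n_events`, `fs`.
#' @export
event_aligned <- function(rec, channel = "470", pre_s = 2, post_s = 5,
                          baseline_s = 120) {
  tab <- dff(rec, channel, pre_s, post_s, baseline_s)
  if (nrow(tab) == 0) stop("no usable event tags", call. = FALSE)
  grid <- seq(-pre_s, post_s, by = 1 / rec$fs)
  tags <- unique(tab$tag_index)
  mat <- t(vapply(tags, function(k) {
    sub <- tab[tab$tag_index == k, ]
    stats::approx(sub$rel_time_s, sub$dff, xout = grid, rule = 2)$y
  }, numeric(length(grid))))
  mean_curve <- colMeans(mat)
  sem_curve <- if (nrow(mat) > 1) {
    apply(mat, 2, stats::sd) / sqrt(nrow(mat))
  } else rep(0, ncol(mat))
  structure(list(matrix = mat, rel_time_s = grid,
                 summary = tibble::tibble(rel_time_s = grid,
                                          mean = mean_curve,
                                          sem = sem_curve),
                 channel = channel, n_events = nrow(mat), fs = rec$fs),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf(
    "<dff_trace> channel %s: %d event(s) x %d samples (%.1f to %.1f s)\n",
    x$channel, x$n_events, length(x$rel_time_s), min(x$rel_time_s),
    max(x$rel_time_s)))
  invisible(x)
}

#' @method tidy dff_trace
#' @export
tidy.dff_trace <- function(x, ...) {
  tibble::tibble(
    event = rep(seq_len(nrow(x$matrix)), each = length(x$rel_time_s)),
    rel_time_s = rep(x$rel_time_s, times = nrow(x$matrix)),
    dff = as.vector(t(x$matrix))
  )
}

#' @method glance dff_trace
#' @export
glance.dff_trace <- function(x, ...) {
  tibble::tibble(channel = x$channel, n_events = x$n_events,
                 peak_mean_dff = max(x$summary$mean),
                 window_lo_s = min(x$rel_time_s),
                 window_hi_s = max(x$rel_time_s))
}

#' Area under the delta-F/F curve
#'
#' Trapezoidal integral of each event's dF/F over `[from_s, to_s]`
#' (relative to the tag), in dF/F x seconds; the post-event window 0 to
#' +5 s is the default.
#'
#' @param trace A `dff_trace` from [event_aligned()].
#' @param from_s,to_s Integration window, seconds relative to the tag.
#' @return A list with `per_event` (tibble: `event`, `auc`) and
#'   `mean_auc`.
#' @export
auc_dff <- function(trace, from_s = 0, to_s = 5) {
  stopifnot(inherits(trace, "dff_trace"))
  if (to_s <= from_s) stop("empty integration window", call. = FALSE)
  if (from_s < min(trace$rel_time_s) - 1e-9 ||
      to_s > max(trace$rel_time_s) + 1e-9) {
    stop("integration window outside the aligned trace span", call. = FALSE)
  }
  sel <- trace$rel_time_s >= from_s - 1e-9 & trace$rel_time_s <= to_s + 1e-9
  tt <- trace$rel_time_s[sel]
  per_event <- tibble::tibble(
    event = seq_len(nrow(trace$matrix)),
    auc = apply(trace$matrix[, sel, drop = FALSE], 1,
                function(y) trapz_integral(tt, y))
  )
  list(per_event = per_event, mean_auc = mean(per_event$auc))
}

#' Isosbestic control check and optional motion correction
#'
#' Reports the per-event correlation between the 470 nm and 410 nm dF/F
#' traces (shared variance indicates motion or other non-calcium
#' artifact), and emits a motion-corrected trace — the 470 dF/F minus a
#' least-squares linear transform of the 410 dF/F fitted on the pre-event
#' (baseline-side) portion of the window — alongside, never replacing, the
#' raw dF/F. If the 410 channel is constant the correction is skipped and
#' reported.
#'
#' @inheritParams event_aligned
#' @return A list with `report` (tibble per event: `event`, `correlation`,
#'   `motion_share`), `corrected` (events x time matrix or `NULL`),
#'   `rel_time_s`, and `correction_applied`.
#' @export
isosbestic_check <- function(rec, pre_s = 2, post_s = 5,
                             baseline_s = 120) {
  a470 <- event_aligned(rec, "470", pre_s, post_s, baseline_s)
  a410 <- event_aligned(rec, "410", pre_s, post_s, baseline_s)
  n_ev <- nrow(a470$matrix)
  pre_idx <- a470$rel_time_s < 0
  const410 <- stats::sd(as.vector(a410$matrix)) < 1e-12
  corrected <- NULL
  if (!const410) {
    corrected <- a470$matrix
    for (k in seq_len(n_ev)) {
      x <- a410$matrix[k, pre_idx]
      y <- a470$matrix[k, pre_idx]
      if (stats::sd(x) < 1e-12) next
      beta <- stats::cov(x, y) / stats::var(x)
      alpha <- mean(y) - beta * mean(x)
      corrected[k, ] <- a470$matrix[k, ] -
        (alpha + beta * a410$matrix[k, ])
    }
  }
  report <- tibble::tibble(
    event = seq_len(n_ev),
    correlation = vapply(seq_len(n_ev), function(k) {
      if (const410 || stats::sd(a410$matrix[k, ]) < 1e-12 ||
          stats::sd(a470$matrix[k, ]) < 1e-12) NA_real_
      else stats::cor(a470$matrix[k, ], a410$matrix[k, ])
    }, 1),
    motion_share = vapply(seq_len(n_ev), function(k) {
      if (const410) return(0)
      v470 <- stats::var(a470$matrix[k, ])
      if (v470 < 1e-24) return(0)
      r <- stats::cor(a470$matrix[k, ], a410$matrix[k, ])
      if (is.na(r)) 0 else r^2
    }, 1)
  )
  list(report = report, corrected = corrected,
       rel_time_s = a470$rel_time_s,
       correction_applied = !const410)
}
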