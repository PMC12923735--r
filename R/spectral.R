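#' Welch power spectral density with a Hann window
#'
#' Averages modified periodograms of Hann-windowed, mean-removed segments
#' with 25% overlap (the configuration used throughout the package). The
#' window length is `2 * (n_freq_values - 1)` samples, giving
#' `n_freq_values` one-sided frequency bins. The estimate is a one-sided
#' density in units^2/Hz, window-power corrected so that its integral over
#' frequency equals the signal variance (Parseval).
#'
#' @param x A [continuous_signal()].
#' @param n_freq_values Number of one-sided frequency bins (default 1024).
#' @param overlap_frac Fractional overlap of adjacent windows (default
#'   0.25).
#' @param window Window name; only `"hann"` is provided.
#' @param per_segment If a positive number of seconds, the PSD is computed
#'   per sequential segment of that length and averaged (`NULL`, the
#'   default, uses the entire recording as one block of Welch windows).
#' @return A `psd_result`: tibble-backed object with columns `freq_hz` and
#'   one power column per channel, plus estimator metadata.
#' @examples
#' x <- continuous_signal(sin(2 * pi * 6 * seq(0, 10, 1e-3)), fs = 1000)
#' p <- welch_psd(x, n_freq_values = 256)
#' band_power(p, band_def("theta", 3, 8))
#' @export
welch_psd <- function(x, n_freq_values = 1024, overlap_frac = 0.25,
                      window = "hann", per_segment = NULL) {
  stopifnot(inherits(x, "continuous_signal"))
  if (!identical(window, "hann")) stop("only the Hann window is supported",
                                       call. = FALSE)
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("`overlap_frac` must lie in [0, 1)", call. = FALSE)
  }
  nwin <- 2L * (as.integer(n_freq_values) - 1L)
  if (nrow(x$data) < nwin) {
    stop(sprintf(
      "signal too short for PSD: need at least %d samples (%g s at %g Hz)",
      nwin, nwin / x$fs, x$fs), call. = FALSE)
  }
  if (!is.null(per_segment)) {
    segs <- segment_signal(x, per_segment)
    segs <- segs[segs$duration_s * x$fs >= nwin, ]
    mats <- lapply(seq_len(nrow(segs)), function(i) {
      xi <- crop_signal(x, segs$start_s[i], segs$end_s[i])
      welch_matrix(xi$data, x$fs, nwin, overlap_frac)$power
    })
    power <- Reduce(`+`, mats) / length(mats)
    freqs <- welch_matrix(x$data[seq_len(nwin), , drop = FALSE], x$fs, nwin,
                          overlap_frac)$freqs
  } else {
    wm <- welch_matrix(x$data, x$fs, nwin, overlap_frac)
    power <- wm$power
    freqs <- wm$freqs
  }
  colnames(power) <- x$channel_ids
  out <- tibble::as_tibble(as.data.frame(power))
  out <- dplyr::bind_cols(tibble::tibble(freq_hz = freqs), out)
  structure(list(table = out, fs = x$fs, n_freq_values = n_freq_values,
                 overlap_frac = overlap_frac, window = "hann",
                 channel_ids = x$channel_ids, units = x$units),
            class = "psd_result")
}

# Core Welch average on a samples x channels matrix.
welch_matrix <- function(mat, fs, nwin, overlap_frac) {
  step <- max(1L, round(nwin * (1 - overlap_frac)))
  starts <- seq(1L, nrow(mat) - nwin + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / (nwin + 1)))  # Hann
  wpow <- sum(w^2)
  nfreq <- nwin / 2 + 1
  scale <- 2 / (fs * wpow)  # one-sided density; DC/Nyquist halved below
  acc <- matrix(0, nfreq, ncol(mat))
  for (s in starts) {
    seg <- mat[s:(s + nwin - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))  # detrend: mean removal per window
    segw <- seg * w
    for (ch in seq_len(ncol(mat))) {
      X <- stats::fft(segw[, ch])[seq_len(nfreq)]
      acc[, ch] <- acc[, ch] + Mod(X)^2
    }
  }
  power <- acc / length(starts) * scale
  power[1, ] <- power[1, ] / 2
  power[nfreq, ] <- power[nfreq, ] / 2
  list(freqs = seq(0, fs / 2, length.out = nfreq), power = power)
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf(
    "<psd_result> %d frequency bins to %g Hz, %d channel(s), Hann/%d%% overlap\n",
    nrow(x$table), max(x$table$freq_hz), length(x$channel_ids),
    round(100 * x$overlap_frac)))
  print(x$table, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PSD estimate into long form
#'
#' @param x A `psd_result`.
#' @param ... Unused.
#' @return A tibble with columns `freq_hz`, `channel`, `power`.
#' @method tidy psd_result
#' @export
tidy.psd_result <- function(x, ...) {
  tidyr::pivot_longer(x$table, -"freq_hz", names_to = "channel",
                      values_to = "power")
}

#' @method glance psd_result
#' @export
glance.psd_result <- function(x, ...) {
  tibble::tibble(n_freq_values = x$n_freq_values, fs = x$fs,
                 overlap_frac = x$overlap_frac, window = x$window,
                 n_channels = length(x$channel_ids))
}

#' Integrated band power from a PSD
#'
#' Trapezoidal integral of the spectral density over `[f_lo, f_hi]`, per
#' channel, in signal units squared. Additive over disjoint bands.
#'
#' @param psd A `psd_result` from [welch_psd()].
#' @param band A [band_def()] within the estimated frequency range, or a
#'   list of them.
#' @return A tibble with columns `band`, `f_lo`, `f_hi`, `channel`,
#'   `power`.
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_result"))
  bands <- if (inherits(band, "band_def")) list(band) else band
  freqs <- psd$table$freq_hz
  purrr::map_dfr(bands, function(b) {
    if (b$f_lo < min(freqs) || b$f_hi > max(freqs)) {
      stop(sprintf("band %s (%g-%g Hz) outside the PSD frequency range",
                   b$name, b$f_lo, b$f_hi), call. = FALSE)
    }
    grid <- sort(unique(c(b$f_lo, freqs[freqs > b$f_lo & freqs < b$f_hi],
                          b$f_hi)))
    purrr::map_dfr(psd$channel_ids, function(ch) {
      p <- stats::approx(freqs, psd$table[[ch]], xout = grid)$y
      tibble::tibble(band = b$name, f_lo = b$f_lo, f_hi = b$f_hi,
                     channel = ch, power = trapz_integral(grid, p))
    })
  })
}

trapz_integral <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Short-time spectrogram
#'
#' Time-frequency power matrix: the Welch/Hann estimator of [welch_psd()]
#' applied to sliding windows, with column times at window centers and the
#' same one-sided density normalization per column.
#'
#' @param x A single- or multi-channel [continuous_signal()]; computed per
#'   requested channel.
#' @param window_s Analysis window length in seconds.
#' @param overlap_frac Fractional overlap between successive windows.
#' @param channel Channel id or index (default first channel).
#' @return A `spectrogram_result` with fields `time_s`, `freq_hz`, `power`
#'   (freq x time matrix).
#' @export
spectrogram <- function(x, window_s = 1, overlap_frac = 0.5,
                        channel = 1) {
  stopifnot(inherits(x, "continuous_signal"))
  ch <- resolve_channel(x, channel)
  nwin <- round(window_s * x$fs)
  if (nwin %% 2 == 1) nwin <- nwin + 1
  if (nrow(x$data) < nwin) stop("signal shorter than one window",
                                call. = FALSE)
  step <- max(1L, round(nwin * (1 - overlap_frac)))
  starts <- seq(1L, nrow(x$data) - nwin + 1L, by = step)
  cols <- vapply(starts, function(s) {
    wm <- welch_matrix(x$data[s:(s + nwin - 1L), ch, drop = FALSE], x$fs,
                       nwin, 0)
    wm$power[, 1]
  }, numeric(nwin / 2 + 1))
  freqs <- seq(0, x$fs / 2, length.out = nwin / 2 + 1)
  structure(list(time_s = x$t0 + (starts - 1 + nwin / 2) / x$fs,
                 freq_hz = freqs, power = cols, channel = x$channel_ids[ch],
                 fs = x$fs),
            class = "spectrogram_result")
}

resolve_channel <- function(x, channel) {
  if (is.character(channel)) {
    ch <- match(channel, x$channel_ids)
    if (is.na(ch)) stop("unknown channel ", channel, call. = FALSE)
    ch
  } else {
    ch <- as.integer(channel)
    if (ch < 1 || ch > ncol(x$data)) stop("channel index out of range",
                                          call. = FALSE)
    ch
  }
}

#' @method tidy spectrogram_result
#' @export
tidy.spectrogram_result <- function(x, ...) {
  tibble::tibble(
    time_s = rep(x$time_s, each = length(x$freq_hz)),
    freq_hz = rep(x$freq_hz, times = length(x$time_s)),
    power = as.vector(x$power)
  )
}

#' @export
print.spectrogram_result <- function(x, ...) {
  cat(sprintf("<spectrogram_result> channel %s: %d freq x %d time bins\n",
              x$channel, length(x$freq_hz), length(x$time_s)))
  invisible(x)
}
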