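#' Extract the phase/amplitude series pair for coupling analysis
#'
#' Band-pass filters one channel in a low (phase-giving) and a high
#' (amplitude-giving) band, takes the analytic signal of each, and returns
#' the low-band instantaneous phase together with the high-band amplitude
#' envelope. An edge margin (default 1 s) is trimmed from both ends to
#' discard filter transients.
#'
#' @param x A [continuous_signal()].
#' @param low,high [band_def()]s for the phase and amplitude bands; must
#'   not overlap (`low$f_hi < high$f_lo`) and must lie below Nyquist.
#' @param channel Channel id or index (default first).
#' @param edge_s Edge margin trimmed from each end, seconds.
#' @return A `pac_series`: tibble-backed object with columns `time_s`,
#'   `phase` (radians, in (-pi, pi]) and `amplitude` (signal units), plus
#'   band metadata.
#' @export
extract_pac_series <- function(x, low = band_presets()$theta_wide,
                               high = band_presets()$gamma, channel = 1,
                               edge_s = 1) {
  stopifnot(inherits(x, "continuous_signal"))
  check_band_nyquist(low, x$fs)
  check_band_nyquist(high, x$fs)
  if (low$f_hi >= high$f_lo) {
    stop("phase and amplitude bands must not overlap (low$f_hi < high$f_lo)",
         call. = FALSE)
  }
  ch <- resolve_channel(x, channel)
  xs <- continuous_signal(x$data[, ch], fs = x$fs, t0 = x$t0, units = x$units)
  lo <- bandpass(xs, low)$data[, 1]
  hi <- bandpass(xs, high)$data[, 1]
  phase <- Arg(analytic_signal(lo))
  amp <- Mod(analytic_signal(hi))
  n <- length(phase)
  margin <- round(edge_s * x$fs)
  keep <- if (n > 2 * margin) (margin + 1):(n - margin) else seq_len(n)
  structure(
    list(table = tibble::tibble(time_s = signal_times(x)[keep],
                                phase = phase[keep],
                                amplitude = amp[keep]),
         fs = x$fs, low_band = low, high_band = high,
         channel = x$channel_ids[ch]),
    class = "pac_series")
}

#' @export
print.pac_series <- function(x, ...) {
  cat(sprintf("<pac_series> %s/%s on channel %s, n = %d\n",
              x$low_band$name, x$high_band$name, x$channel,
              nrow(x$table)))
  invisible(x)
}

#' Phase-amplitude coupling modulation index (mean vector length)
#'
#' Computes the modulation index
#' \deqn{MIn = | n^{-1} \sum_{t=1}^{n} A_t e^{i \theta_t} |}
#' where \eqn{A_t} is the high-band amplitude envelope and \eqn{\theta_t}
#' the low-band phase — the modulus of the amplitude-weighted mean phase
#' phasor. `min_normalized = MIn / mean(A_t)` is the dimensionless variant
#' in `[0, 1]` (0 when the mean amplitude is 0), suitable for comparisons
#' across recordings with different absolute amplitudes.
#'
#' A minimum of about 10 low-band cycles is recommended for a stable
#' estimate; shorter series are accepted with a warning.
#'
#' @param s A `pac_series` from [extract_pac_series()], or a data frame
#'   with `phase` and `amplitude` columns.
#' @return A `pac_result` with fields `min` (signal units),
#'   `min_normalized`, `n`, and band metadata.
#' @examples
#' s <- tibble::tibble(phase = runif(1000, -pi, pi),
#'                     amplitude = rexp(1000))
#' modulation_index(s)
#' @export
modulation_index <- function(s) {
  if (inherits(s, "pac_series")) {
    tab <- s$table
    low <- s$low_band; high <- s$high_band; channel <- s$channel
    fs <- s$fs
  } else {
    tab <- tibble::as_tibble(s)
    if (!all(c("phase", "amplitude") %in% names(tab))) {
      stop("need `phase` and `amplitude` columns", call. = FALSE)
    }
    low <- high <- channel <- fs <- NULL
  }
  n <- nrow(tab)
  if (n == 0) stop("empty phase/amplitude series", call. = FALSE)
  if (any(tab$amplitude < 0)) stop("amplitudes must be non-negative",
                                   call. = FALSE)
  if (!is.null(low) && !is.null(fs)) {
    min_n <- 10 * fs / low$f_lo
    if (n < min_n) {
      warning(sprintf(
        "series covers fewer than 10 low-band cycles (n = %d < %.0f)",
        n, min_n))
    }
  }
  z <- mean(tab$amplitude * exp(1i * tab$phase))
  mi <- Mod(z)
  mean_amp <- mean(tab$amplitude)
  structure(list(min = mi,
                 min_normalized = if (mean_amp > 0) mi / mean_amp else 0,
                 mean_amplitude = mean_amp,
                 preferred_phase = Arg(z),
                 n = n, low_band = low, high_band = high,
                 channel = channel),
            class = "pac_result")
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("<pac_result> MIn = %.6g (normalized %.4f), n = %d\n",
              x$min, x$min_normalized, x$n))
  invisible(x)
}

#' @method tidy pac_result
#' @export
tidy.pac_result <- function(x, ...) {
  tibble::tibble(
    min = x$min,
    min_normalized = x$min_normalized,
    mean_amplitude = x$mean_amplitude,
    preferred_phase = x$preferred_phase,
    n = x$n,
    low_band = if (is.null(x$low_band)) NA_character_ else x$low_band$name,
    high_band = if (is.null(x$high_band)) NA_character_ else x$high_band$name
  )
}

#' @method glance pac_result
#' @export
glance.pac_result <- function(x, ...) tidy(x, ...)

#' Comodulogram: modulation index over a grid of band pairs
#'
#' Evaluates the normalized modulation index for every (phase band,
#' amplitude band) pair in the supplied grids.
#'
#' @param x A [continuous_signal()].
#' @param low_grid,high_grid Lists of [band_def()]s for the phase and
#'   amplitude axes.
#' @param channel Channel id or index.
#' @param edge_s Edge margin passed to [extract_pac_series()].
#' @param surrogates Number of circular-shift surrogates used to attach an
#'   empirical null level per cell (0 disables, the default).
#' @param min_shift_s Minimum circular shift of the amplitude series for
#'   surrogates, seconds.
#' @param seed Seed for the surrogate shifts.
#' @return A `comodulogram_result`; `tidy()` gives a tibble with one row
#'   per cell (`low_band`, `high_band`, `min_normalized`, and when
#'   surrogates are requested, `null_mean`, `null_sd`).
#' @export
comodulogram <- function(x, low_grid, high_grid, channel = 1, edge_s = 1,
                         surrogates = 0, min_shift_s = 1, seed = 1) {
  stopifnot(inherits(x, "continuous_signal"))
  cells <- purrr::map_dfr(seq_along(low_grid), function(i) {
    lo <- low_grid[[i]]
    purrr::map_dfr(seq_along(high_grid), function(j) {
      hi <- high_grid[[j]]
      s <- extract_pac_series(x, lo, hi, channel = channel, edge_s = edge_s)
      res <- modulation_index(s)
      row <- tibble::tibble(
        low_band = lo$name, low_lo = lo$f_lo, low_hi = lo$f_hi,
        high_band = hi$name, high_lo = hi$f_lo, high_hi = hi$f_hi,
        min = res$min, min_normalized = res$min_normalized)
      if (surrogates > 0) {
        null_vals <- surrogate_min(s, surrogates, min_shift_s,
                                   seed + 7919L * i + j)
        row$null_mean <- mean(null_vals)
        row$null_sd <- stats::sd(null_vals)
      }
      row
    })
  })
  structure(list(table = cells, channel = channel,
                 n_low = length(low_grid), n_high = length(high_grid)),
            class = "comodulogram_result")
}

# Circular time-shift surrogate null: shift the amplitude series by at
# least min_shift_s, preserving its autocorrelation, and recompute the
# normalized modulation index.
surrogate_min <- function(s, n_surr, min_shift_s, seed) {
  tab <- s$table
  n <- nrow(tab)
  min_shift <- round(min_shift_s * s$fs)
  if (2 * min_shift >= n) min_shift <- floor(n / 4)
  with_local_seed(seed, {
    shifts <- sample(seq(min_shift, n - min_shift), n_surr, replace = TRUE)
    vapply(shifts, function(k) {
      amp <- c(tab$amplitude[(k + 1):n], tab$amplitude[1:k])
      z <- mean(amp * exp(1i * tab$phase))
      Mod(z) / mean(amp)
    }, 1)
  })
}

#' @method tidy comodulogram_result
#' @export
tidy.comodulogram_result <- function(x, ...) x$table

#' @export
print.comodulogram_result <- function(x, ...) {
  cat(sprintf("<comodulogram_result> %d x %d band pairs\n",
              x$n_low, x$n_high))
  print(x$table, ...)
  invisible(x)
}

#' Build a regular grid of adjacent bands
#'
#' Convenience for comodulogram axes: splits `[f_min, f_max]` into `n`
#' adjacent bands of equal width.
#'
#' @param f_min,f_max Range in Hz.
#' @param n Number of bands.
#' @param prefix Name prefix for the bands.
#' @return A list of [band_def()]s.
#' @export
band_grid <- function(f_min, f_max, n, prefix = "band") {
  edges <- seq(f_min, f_max, length.out = n + 1)
  lapply(seq_len(n), function(i) {
    band_def(sprintf("%s_%g_%g", prefix, edges[i], edges[i + 1]),
             edges[i], edges[i + 1])
  })
}
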