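# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a power spectral density estimate
#'
#' @param object A `psd_result`.
#' @param log_power Plot power on a log10 axis (default TRUE).
#' @param max_freq_hz Upper frequency limit; `NULL` shows the full range.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psd_result
#' @export
autoplot.psd_result <- function(object, log_power = TRUE,
                                max_freq_hz = NULL, ...) {
  df <- tidy(object)
  if (!is.null(max_freq_hz)) df <- df[df$freq_hz <= max_freq_hz, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz,
                                        y = .data$power,
                                        colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = sprintf("Power (%s²/Hz)", object$units),
                  colour = "Channel") +
    ggplot2::theme_minimal()
  if (log_power) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a spectrogram
#'
#' @param object A `spectrogram_result`.
#' @param max_freq_hz Upper frequency limit.
#' @param ... Unused.
#' @return A ggplot (log10 power fill).
#' @method autoplot spectrogram_result
#' @export
autoplot.spectrogram_result <- function(object, max_freq_hz = NULL, ...) {
  df <- tidy(object)
  if (!is.null(max_freq_hz)) df <- df[df$freq_hz <= max_freq_hz, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = log10(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a comodulogram
#'
#' @param object A `comodulogram_result`.
#' @param ... Unused.
#' @return A ggplot tile map of normalized modulation index over band
#'   pairs.
#' @method autoplot comodulogram_result
#' @export
autoplot.comodulogram_result <- function(object, ...) {
  df <- tidy(object)
  df$low_mid <- (df$low_lo + df$low_hi) / 2
  df$high_mid <- (df$high_lo + df$high_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$low_mid, y = .data$high_mid,
                                   fill = .data$min_normalized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "MIn (norm.)") +
    ggplot2::labs(x = "Phase band center (Hz)",
                  y = "Amplitude band center (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot an event-aligned delta-F/F summary
#'
#' Mean curve with a SEM ribbon over the event window.
#'
#' @param object A `dff_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dff_trace
#' @export
autoplot.dff_trace <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time from event (s)",
                  y = expression(Delta * F / F[0])) +
    ggplot2::theme_minimal()
}

#' Plot detected events over a signal trace
#'
#' @param x A [continuous_signal()].
#' @param events An event tibble from a detector.
#' @param channel Channel to draw.
#' @return A ggplot of the trace with shaded event intervals.
#' @export
plot_events <- function(x, events, channel = 1) {
  ch <- resolve_channel(x, channel)
  df <- tibble::tibble(time_s = signal_times(x), value = x$data[, ch])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                        y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = x$units) +
    ggplot2::theme_minimal()
  if (nrow(events)) {
    p <- p + ggplot2::geom_rect(
      data = events,
      ggplot2::aes(xmin = .data$t_on, xmax = .data$t_off,
                   fill = .data$kind),
      ymin = -Inf, ymax = Inf, alpha = 0.25, inherit.aes = FALSE)
  }
  p
}

#' @importFrom rlang .data
NULL
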