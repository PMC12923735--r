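#' Read a continuous signal from disk
#'
#' Two on-disk layouts are supported:
#' * `"csv"` — one column per channel, optional leading `time_s` column.
#'   A JSON sidecar (`<path>.json`) supplies `fs` and metadata; when absent,
#'   `fs` is inferred from the time column.
#' * `"raw_f32"` — channel-major little-endian float32 stream, with a
#'   mandatory JSON sidecar giving `fs`, `n_channels`, `channel_ids`,
#'   `units`, `geometry`, `t0`. Round-trips with [write_signal()] bit
#'   exactly at float32 precision.
#'
#' @param path File to read.
#' @param format `"csv"` or `"raw_f32"`.
#' @return A validated [continuous_signal()].
#' @export
read_signal <- function(path, format = c("csv", "raw_f32")) {
  format <- match.arg(format)
  sidecar_path <- paste0(path, ".json")
  if (format == "raw_f32") {
    if (!file.exists(sidecar_path)) {
      stop("raw_f32 requires a JSON sidecar at ", sidecar_path, call. = FALSE)
    }
    meta <- read_sidecar(sidecar_path)
    n <- file.size(path) / 4
    vals <- readBin(path, what = "numeric", n = n, size = 4, endian = "little")
    if (length(vals) %% meta$n_channels != 0) {
      stop("raw_f32 stream length is not a multiple of n_channels",
           call. = FALSE)
    }
    # channel-major: all of channel 1, then channel 2, ...
    mat <- matrix(vals, ncol = meta$n_channels)
    continuous_signal(mat, fs = meta$fs, t0 = meta$t0,
                      channel_ids = meta$channel_ids,
                      geometry = meta$geometry, units = meta$units)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    meta <- if (file.exists(sidecar_path)) read_sidecar(sidecar_path) else NULL
    has_time <- "time_s" %in% names(df)
    if (is.null(meta) && !has_time) {
      stop("csv without sidecar must contain a `time_s` column", call. = FALSE)
    }
    if (has_time) {
      tcol <- df$time_s
      df <- df[setdiff(names(df), "time_s")]
    }
    fs <- if (!is.null(meta)) meta$fs else 1 / stats::median(diff(tcol))
    t0 <- if (!is.null(meta)) meta$t0 else tcol[1]
    mat <- as.matrix(df)
    if (!is.numeric(mat)) stop("non-numeric channel data in csv", call. = FALSE)
    continuous_signal(
      mat, fs = fs, t0 = t0,
      channel_ids = if (!is.null(meta)) meta$channel_ids else names(df),
      geometry = if (!is.null(meta)) meta$geometry else NULL,
      units = if (!is.null(meta)) meta$units else "uV")
  }
}

read_sidecar <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("fs")) {
    if (is.null(meta[[field]])) {
      stop("sidecar missing required field `", field, "`", call. = FALSE)
    }
  }
  if (meta$fs <= 0) stop("sidecar fs must be positive", call. = FALSE)
  if (is.null(meta$t0)) meta$t0 <- 0
  if (is.null(meta$units)) meta$units <- "uV"
  if (is.null(meta$n_channels) && !is.null(meta$channel_ids)) {
    meta$n_channels <- length(meta$channel_ids)
  }
  if (is.null(meta$channel_ids) && !is.null(meta$n_channels)) {
    meta$channel_ids <- paste0("ch", seq_len(meta$n_channels))
  }
  if (!is.null(meta$geometry)) {
    if (is.matrix(meta$geometry)) {
      meta$geometry <- lapply(seq_len(nrow(meta$geometry)),
                              function(i) meta$geometry[i, ])
    }
  }
  meta
}

#' Write a continuous signal to disk
#'
#' Writes the signal in the layout described in [read_signal()], plus the
#' JSON sidecar `<path>.json`.
#'
#' @param x A [continuous_signal()].
#' @param path Output file.
#' @param format `"csv"` or `"raw_f32"`.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, format = c("csv", "raw_f32")) {
  stopifnot(inherits(x, "continuous_signal"))
  format <- match.arg(format)
  meta <- list(fs = x$fs, t0 = x$t0, n_channels = ncol(x$data),
               channel_ids = x$channel_ids, units = x$units,
               geometry = x$geometry)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (format == "raw_f32") {
    writeBin(as.vector(x$data), path, size = 4, endian = "little")
  } else {
    df <- data.frame(time_s = signal_times(x), x$data, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
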