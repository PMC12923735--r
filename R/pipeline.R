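# Single-config orchestration: simulate -> spectral -> coupling -> events
# -> spikes -> photometry, with a machine-readable, reproducible report.

#' Build a validated pipeline configuration
#'
#' A run configuration names the synthetic recording conditions and every
#' analysis parameter; all analysis defaults match the package defaults.
#' Unknown keys are rejected so config typos cannot silently change a run.
#'
#' @param seed Master integer seed; per-stage seeds are derived from it
#'   (see [child_seed()]).
#' @param lfp Named list of [lfp_spec()] arguments; `events` may be given
#'   as a list of plain lists (JSON-friendly) with the [event_spec()]
#'   fields.
#' @param bands Character vector of [band_presets()] names to integrate
#'   band power over.
#' @param pac Named list: `low`, `high` (preset names), `channel`.
#' @param epileptiform Named list of [detect_epileptiform()] arguments.
#' @param ripples,fast_ripples Named lists of detector arguments, or
#'   `NULL` to skip.
#' @param spikes Named list of [spike_pop_spec()] arguments, or `NULL` to
#'   skip the spike stage.
#' @param photometry Named list of [photo_spec()] arguments, or `NULL` to
#'   skip the photometry stage.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1,
                       lfp = list(),
                       bands = c("theta", "low_gamma", "high_gamma"),
                       pac = list(low = "theta_wide", high = "gamma",
                                  channel = 1),
                       epileptiform = list(),
                       ripples = list(),
                       fast_ripples = list(),
                       spikes = NULL,
                       photometry = NULL) {
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop("unknown config key(s) in ", where, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(lfp, names(formals(lfp_spec)), "lfp")
  check_keys(pac, c("low", "high", "channel", "edge_s"), "pac")
  check_keys(epileptiform,
             setdiff(names(formals(detect_epileptiform)), "x"),
             "epileptiform")
  for (nm in c("ripples", "fast_ripples")) {
    check_keys(get(nm), c("channel", "envelope_sd_mult", "merge_gap_ms",
                          "smooth_sigma_ms"), nm)
  }
  if (!is.null(spikes)) {
    check_keys(spikes, names(formals(spike_pop_spec)), "spikes")
  }
  if (!is.null(photometry)) {
    check_keys(photometry, names(formals(photo_spec)), "photometry")
  }
  bad <- setdiff(bands, names(band_presets()))
  if (length(bad)) stop("unknown band preset(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(seed = as.integer(seed), lfp = lfp, bands = bands,
                 pac = pac, epileptiform = epileptiform,
                 ripples = ripples, fast_ripples = fast_ripples,
                 spikes = spikes, photometry = photometry),
            class = "run_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file.
#' @return For `read_run_config`, a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(raw$lfp$events)) {
    raw$lfp$events <- lapply(raw$lfp$events,
                             function(e) do.call(event_spec, e))
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  if (!is.null(x$lfp$events)) {
    x$lfp$events <- lapply(x$lfp$events, unclass)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Derive a per-stage child seed from the master seed
#'
#' `child = (seed * 7919 + sum of the stage name's character codes) mod
#' (2^31 - 1)`. Each pipeline stage consumes its own child seed, so stages
#' are independently reproducible.
#'
#' @param seed Master integer seed.
#' @param stage Stage name.
#' @return An integer seed.
#' @export
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + sum(utf8ToInt(stage))) %%
               (2^31 - 1))
}

#' Run the full analysis pipeline from one configuration
#'
#' Simulates the configured recordings and executes the analysis stages in
#' dependency order: PSD band powers, phase-amplitude coupling, event
#' detection (epileptiform, ripple, fast ripple), spike analysis, and
#' photometry. All randomness flows from the single master seed through
#' [child_seed()]; the same configuration yields an identical report
#' (excluding the timestamp — compare with [report_fingerprint()]).
#'
#' @param config A [run_config()].
#' @return A `run_report`: list with `config`, `config_hash`,
#'   `band_power`, `pac`, `events` (per-kind summaries + event tables),
#'   `units`, `photometry`, `version`, `warnings`, `timestamp`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warn <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  presets <- band_presets()

  sim <- gen_lfp(do.call(lfp_spec, config$lfp),
                 seed = child_seed(config$seed, "lfp"))
  sig <- sim$signal

  p <- collect(welch_psd(sig, n_freq_values = min(
    1024, floor(nrow(sig$data) / 2) + 1)))
  bp <- band_power(p, presets[config$bands])

  pac_args <- config$pac
  s <- extract_pac_series(sig, presets[[pac_args$low %||% "theta_wide"]],
                          presets[[pac_args$high %||% "gamma"]],
                          channel = pac_args$channel %||% 1,
                          edge_s = pac_args$edge_s %||% 1)
  pac_res <- tidy(modulation_index(s))

  epi <- collect(do.call(detect_epileptiform,
                         c(list(x = sig), config$epileptiform)))
  rip <- collect(do.call(detect_ripples, c(list(x = sig), config$ripples)))
  fr_band_ok <- presets$fast_ripple$f_hi < sig$fs / 2
  fr <- if (fr_band_ok) {
    collect(do.call(detect_fast_ripples,
                    c(list(x = sig), config$fast_ripples)))
  } else empty_events()
  if (!fr_band_ok) warn <- c(warn, "fast-ripple band above Nyquist; skipped")
  rip_clean <- exclude_overlapping(rip, epi)
  dur <- signal_duration(sig)
  events <- list(
    epileptiform = summarize_events(epi, dur),
    ripple = summarize_events(rip_clean, dur),
    fast_ripple = summarize_events(exclude_overlapping(fr, epi), dur),
    tables = list(epileptiform = epi, ripple = rip, fast_ripple = fr)
  )

  units_tab <- NULL
  if (!is.null(config$spikes)) {
    sp <- gen_spike_units(do.call(spike_pop_spec, config$spikes),
                          seed = child_seed(config$seed, "spikes"))
    units <- lapply(sp$units, qc_unit)
    units_tab <- collect(classify_units(units,
                                        seed = child_seed(config$seed,
                                                          "classify")))
    units_tab$true_label <- sp$truth$label
  }

  photo <- NULL
  if (!is.null(config$photometry)) {
    ph <- gen_photometry(do.call(photo_spec, config$photometry),
                         seed = child_seed(config$seed, "photometry"))
    if (length(ph$recording$event_tags)) {
      al <- collect(event_aligned(ph$recording, "470"))
      photo <- list(auc = auc_dff(al), mean_curve = al$summary,
                    n_events = al$n_events)
    }
  }

  report <- list(
    config = config,
    config_hash = rlang::hash(unclass(config)),
    band_power = bp,
    pac = pac_res,
    events = events,
    units = units_tab,
    photometry = photo,
    version = as.character(utils::packageVersion("neuropac")),
    warnings = warn,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$config_hash, "\n")
  cat(" band power rows:", nrow(x$band_power),
      "| MIn_normalized:", signif(x$pac$min_normalized, 4), "\n")
  cat(" epileptiform rate/min:",
      signif(x$events$epileptiform$overall$event_rate_per_min, 4), "\n")
  invisible(x)
}

#' Content fingerprint of a run report
#'
#' Hash of the report excluding its timestamp; two runs of the same
#' configuration and seed have identical fingerprints.
#'
#' @param report A `run_report`.
#' @return A character hash.
#' @export
report_fingerprint <- function(report) {
  stopifnot(inherits(report, "run_report"))
  report$timestamp <- NULL
  rlang::hash(unclass(report))
}

#' Descriptive comparison of two pipeline runs
#'
#' Differences and ratios of the headline quantities of two reports run
#' under the same parameterization (band presets must match). Purely
#' descriptive — no inferential statistics. Ratios with a zero denominator
#' are reported as `NA`, not infinity.
#'
#' @param report_a,report_b `run_report`s.
#' @return A tibble: `metric`, `value_a`, `value_b`, `difference`,
#'   `ratio`.
#' @export
compare_conditions <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "run_report"),
            inherits(report_b, "run_report"))
  if (!identical(report_a$config$bands, report_b$config$bands)) {
    stop("reports use different band presets and cannot be compared",
         call. = FALSE)
  }
  grab <- function(r) {
    bp <- r$band_power
    bp_mean <- stats::aggregate(power ~ band, data = bp, FUN = mean)
    vals <- stats::setNames(bp_mean$power,
                            paste0("band_power_", bp_mean$band))
    c(vals,
      min_normalized = r$pac$min_normalized,
      epileptiform_rate_per_min =
        r$events$epileptiform$overall$event_rate_per_min,
      ripple_rate_per_min = r$events$ripple$overall$event_rate_per_min,
      ripple_intra_freq_hz =
        r$events$ripple$overall$mean_intra_freq_hz,
      ripple_peak_amplitude =
        r$events$ripple$overall$mean_peak_amplitude,
      fast_ripple_rate_per_min =
        r$events$fast_ripple$overall$event_rate_per_min)
  }
  a <- grab(report_a); b <- grab(report_b)
  metrics <- union(names(a), names(b))
  tibble::tibble(
    metric = metrics,
    value_a = unname(a[metrics]),
    value_b = unname(b[metrics]),
    difference = unname(b[metrics] - a[metrics]),
    ratio = unname(ifelse(!is.na(a[metrics]) & a[metrics] != 0,
                          b[metrics] / a[metrics], NA_real_))
  )
}
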