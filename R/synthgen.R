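# Seeded generators for LFP, spike-band, and photometry data with known
# ground truth. All randomness is local: generators save and restore the
# global RNG state and use R's default Mersenne-Twister, so a given
# (spec, seed) pair reproduces bit-identically across platforms.

with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Raised-cosine (Tukey) envelope; short ramps (alpha 0.1 => 5% taper per
# side) preserve the nominal event duration while avoiding edge ringing.
tukey_window <- function(n, alpha = 0.1) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}

# 1/f^beta noise by spectral shaping of white Gaussian noise; exact exponent
# control, scaled to the requested standard deviation.
colored_noise <- function(n, beta, sd, fs) {
  if (sd <= 0) return(numeric(n))
  white <- stats::rnorm(n)
  if (beta == 0) return(white * sd)
  X <- stats::fft(white)
  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]  # fold to physical freq
  shape <- c(0, freqs[-1]^(-beta / 2))
  x <- Re(stats::fft(X * shape, inverse = TRUE) / n)
  x / stats::sd(x) * sd
}

# LFP ---------------------------------------------------------------------

#' Specification for a synthetic local field potential recording
#'
#' Describes a multi-channel 1 kHz-class LFP with a 1/f^beta background, a
#' theta rhythm, theta-phase-modulated gamma, and optional injected
#' oscillatory events (epileptiform bursts, ripples, fast ripples). Default
#' amplitudes are on a microvolt scale typical of mouse CA1 wire-array
#' recordings.
#'
#' The gamma component is amplitude-modulated by theta phase as
#' `gamma_amp * (1 + m * cos(theta_phase - phi)) / (1 + m)`, so `m = 0`
#' gives constant gamma amplitude and `m = 1` gives full-depth modulation
#' with the envelope maximal at theta phase `phi`.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Recording length, seconds.
#' @param theta_hz,theta_amp Theta frequency (Hz) and amplitude (uV).
#' @param gamma_hz,gamma_amp Gamma frequency (Hz) and mean amplitude (uV).
#' @param coupling_depth Modulation depth `m` in `[0, 1]`.
#' @param coupling_phase Theta phase (radians) at which the gamma envelope
#'   peaks.
#' @param noise_exponent Background spectral exponent beta (power ~
#'   1/f^beta).
#' @param noise_sd Background standard deviation (uV).
#' @param n_channels Number of recording channels (default 8, a 4 x 2 wire
#'   array read out in linear contiguity order).
#' @param shared_fraction Fraction of signal variance common to all channels
#'   (oscillatory components are always shared; this mixes the background).
#' @param events A list of [event_spec()] objects to inject.
#' @return An `lfp_spec` object.
#' @export
lfp_spec <- function(fs = 1000, duration_s = 120, theta_hz = 6,
                     theta_amp = 50, gamma_hz = 40, gamma_amp = 20,
                     coupling_depth = 0.5, coupling_phase = 0,
                     noise_exponent = 1, noise_sd = 15, n_channels = 8,
                     shared_fraction = 0.5, events = list()) {
  if (coupling_depth < 0 || coupling_depth > 1) {
    stop("`coupling_depth` must lie in [0, 1]", call. = FALSE)
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("`shared_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (fs <= 2 * max(theta_hz, gamma_hz,
                    vapply(events, function(e) e$carrier_hz, 1))) {
    stop("`fs` must exceed twice the highest generated frequency",
         call. = FALSE)
  }
  for (e in events) {
    if (!inherits(e, "event_spec")) stop("events must be event_spec objects",
                                         call. = FALSE)
    if (e$t_on + e$duration_s > duration_s) {
      stop("event extends beyond the recording", call. = FALSE)
    }
    if (any(e$channels > n_channels)) {
      stop("event channel index exceeds n_channels", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "lfp_spec")
}

#' Specification for one injected oscillatory event
#'
#' @param kind `"epileptiform"`, `"ripple"`, or `"fast_ripple"`.
#' @param t_on Onset, seconds.
#' @param duration_s Duration, seconds.
#' @param carrier_hz Carrier frequency; must lie in the band conventional
#'   for its kind (ripple 140-200 Hz, fast ripple 200-500 Hz, epileptiform
#'   > 100 Hz).
#' @param amplitude Peak carrier amplitude in multiples of the background
#'   standard deviation.
#' @param channels Integer channel indices carrying the event.
#' @return An `event_spec` object.
#' @export
event_spec <- function(kind = c("epileptiform", "ripple", "fast_ripple"),
                       t_on, duration_s, carrier_hz, amplitude,
                       channels) {
  kind <- match.arg(kind)
  ok <- switch(kind,
    ripple = carrier_hz >= 140 && carrier_hz <= 200,
    fast_ripple = carrier_hz >= 200 && carrier_hz <= 500,
    epileptiform = carrier_hz > 100
  )
  if (!ok) stop("carrier_hz outside the conventional band for kind ", kind,
                call. = FALSE)
  if (duration_s <= 0 || amplitude <= 0 || length(channels) < 1) {
    stop("invalid event_spec", call. = FALSE)
  }
  structure(list(kind = kind, t_on = t_on, duration_s = duration_s,
                 carrier_hz = carrier_hz, amplitude = amplitude,
                 channels = as.integer(channels)),
            class = "event_spec")
}

#' Generate a synthetic LFP recording with ground truth
#'
#' @param spec An [lfp_spec()].
#' @param seed Integer seed; the same (spec, seed) pair is bit-reproducible.
#' @return A list with elements `signal` (a [continuous_signal()]) and
#'   `truth` — a list holding `events` (tibble: kind, t_on, t_off,
#'   duration_s, carrier_hz, amplitude, channels), `coupling`
#'   (theta/gamma frequencies, depth `m`, phase), and `theta_phase`
#'   (the exact generated phase series).
#' @examples
#' sim <- gen_lfp(lfp_spec(duration_s = 10), seed = 1)
#' sim$signal
#' @export
gen_lfp <- function(spec, seed) {
  stopifnot(inherits(spec, "lfp_spec"))
  with_local_seed(seed, {
    n <- round(spec$duration_s * spec$fs)
    t <- (seq_len(n) - 1) / spec$fs
    theta_phase <- 2 * pi * spec$theta_hz * t
    theta <- spec$theta_amp * cos(theta_phase)
    m <- spec$coupling_depth
    gam_env <- spec$gamma_amp *
      (1 + m * cos(theta_phase - spec$coupling_phase)) / (1 + m)
    gamma <- gam_env * cos(2 * pi * spec$gamma_hz * t)
    osc <- theta + gamma

    shared_bg <- colored_noise(n, spec$noise_exponent, spec$noise_sd, spec$fs)
    a <- sqrt(spec$shared_fraction)
    b <- sqrt(1 - spec$shared_fraction)
    mat <- matrix(0, n, spec$n_channels)
    for (ch in seq_len(spec$n_channels)) {
      own <- colored_noise(n, spec$noise_exponent, spec$noise_sd, spec$fs)
      mat[, ch] <- osc + a * shared_bg + b * own
    }

    for (e in spec$events) {
      i0 <- round(e$t_on * spec$fs) + 1
      len <- round(e$duration_s * spec$fs)
      idx <- i0:(i0 + len - 1)
      burst <- e$amplitude * spec$noise_sd * tukey_window(len) *
        sin(2 * pi * e$carrier_hz * (seq_len(len) - 1) / spec$fs)
      for (ch in e$channels) mat[idx, ch] <- mat[idx, ch] + burst
    }

    sig <- continuous_signal(mat, fs = spec$fs, units = "uV")
    truth_events <- tibble::tibble(
      kind = vapply(spec$events, `[[`, "", "kind"),
      t_on = vapply(spec$events, `[[`, 1, "t_on"),
      duration_s = vapply(spec$events, `[[`, 1, "duration_s"),
      t_off = .data_t_off(spec$events),
      carrier_hz = vapply(spec$events, `[[`, 1, "carrier_hz"),
      amplitude = vapply(spec$events, `[[`, 1, "amplitude"),
      channels = lapply(spec$events, `[[`, "channels")
    )
    list(signal = sig,
         truth = list(events = truth_events,
                      coupling = list(theta_hz = spec$theta_hz,
                                      gamma_hz = spec$gamma_hz,
                                      m = m, phase = spec$coupling_phase),
                      theta_phase = theta_phase))
  })
}

.data_t_off <- function(events) {
  vapply(events, function(e) e$t_on + e$duration_s, 1)
}

# Spikes ------------------------------------------------------------------

#' Specification for synthetic spike-band recordings and unit populations
#'
#' `classes` describes one row per unit class (conventionally fast-spiking
#' and regular-spiking): firing rate, waveform shape parameters, amplitude
#' (in multiples of the noise SD), and the number of units. The waveform
#' template is biphasic — a negative Gaussian trough whose full width at
#' half depth is `half_width_ms`, followed by a positive peak
#' `trough_to_peak_ms` later with amplitude `peak_valley_ratio` times the
#' trough depth.
#'
#' @param classes A data frame with columns `label`, `rate_hz`,
#'   `trough_to_peak_ms`, `half_width_ms`, `peak_valley_ratio`,
#'   `amplitude_sd`, `n_units`.
#' @param refractory_ms Absolute refractory period (hard dead time) of the
#'   renewal spike trains.
#' @param noise_sd Additive Gaussian noise SD of the spike band (uV).
#' @param fs Sampling rate, Hz (default 40 kHz).
#' @param duration_s Recording length, seconds.
#' @return A `spike_pop_spec` object.
#' @export
spike_pop_spec <- function(classes = default_spike_classes(),
                           refractory_ms = 1.5, noise_sd = 5,
                           fs = 40000, duration_s = 60) {
  classes <- tibble::as_tibble(classes)
  need <- c("label", "rate_hz", "trough_to_peak_ms", "half_width_ms",
            "peak_valley_ratio", "amplitude_sd", "n_units")
  if (!all(need %in% names(classes))) {
    stop("`classes` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(classes$rate_hz <= 0)) stop("rates must be positive", call. = FALSE)
  if (refractory_ms < 0) stop("refractory_ms must be >= 0", call. = FALSE)
  if (any(refractory_ms / 1000 >= 1 / classes$rate_hz)) {
    stop("refractory period >= mean ISI: requested rate is unrealizable",
         call. = FALSE)
  }
  structure(list(classes = classes, refractory_ms = refractory_ms,
                 noise_sd = noise_sd, fs = fs, duration_s = duration_s),
            class = "spike_pop_spec")
}

#' @rdname spike_pop_spec
#' @export
default_spike_classes <- function() {
  tibble::tibble(
    label = c("FS", "RS"),
    rate_hz = c(20, 2),
    trough_to_peak_ms = c(0.35, 0.8),
    half_width_ms = c(0.2, 0.5),
    peak_valley_ratio = c(0.35, 0.55),
    amplitude_sd = c(8, 8),
    n_units = c(1L, 1L)
  )
}

# Biphasic waveform template sampled at fs over window_ms around the
# trough: a negative Gaussian lobe at 0 (FWHM = half_width_ms) and a
# positive raised-cosine lobe centered at trough_to_peak_ms. The positive
# lobe has compact support that excludes the trough region, so the
# trough's depth and half-width are exact by construction; the two lobe
# amplitudes solve a 2x2 linear system so the residual tail overlap still
# leaves the value at 0 exactly -depth and at trough_to_peak_ms exactly
# peak_valley_ratio * depth.
spike_template <- function(trough_to_peak_ms, half_width_ms,
                           peak_valley_ratio, depth, fs,
                           window_ms = c(-0.5, 1.5)) {
  t_ms <- seq(window_ms[1], window_ms[2], by = 1000 / fs)
  sig_tr <- half_width_ms / (2 * sqrt(2 * log(2)))
  w_pk <- min(max(0.75 * trough_to_peak_ms, half_width_ms),
              0.9 * trough_to_peak_ms)
  lobe <- function(t) {
    ifelse(abs(t - trough_to_peak_ms) < w_pk,
           cos(pi * (t - trough_to_peak_ms) / (2 * w_pk))^2, 0)
  }
  k_pk_at_tr <- lobe(0)
  k_tr_at_pk <- exp(-trough_to_peak_ms^2 / (2 * sig_tr^2))
  det <- 1 - k_pk_at_tr * k_tr_at_pk
  a_tr <- depth * (1 + peak_valley_ratio * k_pk_at_tr) / det
  a_pk <- depth * (peak_valley_ratio + k_tr_at_pk) / det
  -a_tr * exp(-t_ms^2 / (2 * sig_tr^2)) + a_pk * lobe(t_ms)
}

# Renewal train: exponential ISIs plus a hard dead time (Poisson-with-dead-
# time); mean rate is preserved by shrinking the exponential mean.
renewal_train <- function(rate_hz, refractory_s, duration_s) {
  mean_exp <- 1 / rate_hz - refractory_s
  n_guess <- max(10, ceiling(duration_s * rate_hz * 1.5 + 20))
  isis <- refractory_s + stats::rexp(n_guess, rate = 1 / mean_exp)
  ts <- cumsum(isis)
  while (ts[length(ts)] < duration_s) {
    more <- refractory_s + stats::rexp(n_guess, rate = 1 / mean_exp)
    ts <- c(ts, ts[length(ts)] + cumsum(more))
  }
  ts[ts < duration_s]
}

#' Generate a continuous spike-band recording with ground truth
#'
#' Each unit is assigned its own channel (single-template-per-channel
#' convention for synthetic data); spike trains are renewal processes with a
#' hard absolute refractory period, and each spike adds a scaled biphasic
#' template into white noise of known SD.
#'
#' @param spec A [spike_pop_spec()].
#' @param seed Integer seed.
#' @return A list with `signal` (40 kHz-class [continuous_signal()], one
#'   channel per unit) and `truth` (tibble: `unit`, `channel`, `label`,
#'   `timestamps` list-column, plus the per-unit template parameters).
#' @export
gen_spikes <- function(spec, seed) {
  stopifnot(inherits(spec, "spike_pop_spec"))
  with_local_seed(seed, {
    units <- expand_units(spec$classes)
    n_units <- nrow(units)
    n <- round(spec$duration_s * spec$fs)
    mat <- matrix(stats::rnorm(n * n_units, sd = spec$noise_sd), n, n_units)
    timestamps <- vector("list", n_units)
    half_pre <- round(0.5e-3 * spec$fs)
    for (u in seq_len(n_units)) {
      ts <- renewal_train(units$rate_hz[u], spec$refractory_ms / 1000,
                          spec$duration_s)
      tmpl <- spike_template(units$trough_to_peak_ms[u],
                             units$half_width_ms[u],
                             units$peak_valley_ratio[u],
                             depth = units$amplitude_sd[u] * spec$noise_sd,
                             fs = spec$fs)
      len <- length(tmpl)
      for (s in ts) {
        i0 <- round(s * spec$fs) + 1 - half_pre
        if (i0 < 1 || i0 + len - 1 > n) next
        idx <- i0:(i0 + len - 1)
        mat[idx, u] <- mat[idx, u] + tmpl
      }
      timestamps[[u]] <- ts
    }
    sig <- continuous_signal(mat, fs = spec$fs, units = "uV")
    truth <- dplyr::mutate(units, unit = dplyr::row_number(),
                           channel = paste0("ch", unit),
                           timestamps = timestamps)
    list(signal = sig, truth = truth)
  })
}

expand_units <- function(classes) {
  rows <- rep(seq_len(nrow(classes)), classes$n_units)
  units <- classes[rows, setdiff(names(classes), "n_units")]
  tibble::as_tibble(units)
}

#' Generate a population of spike units directly (no continuous trace)
#'
#' Builds [spike_unit()] objects for a whole population: renewal-process
#' timestamps and per-spike waveforms (template plus white noise), with
#' small per-unit log-normal jitter (5%) on rate and waveform parameters so
#' units within a class are not identical. Used for classifier recovery
#' studies where simulating tens of continuous 40 kHz channels would serve
#' no purpose.
#'
#' @param spec A [spike_pop_spec()].
#' @param seed Integer seed.
#' @param unit_jitter Log-normal SD of per-unit parameter jitter
#'   (default 0.05).
#' @return A list with `units` (list of [spike_unit()]) and `truth`
#'   (tibble of true labels and parameters).
#' @export
gen_spike_units <- function(spec, seed, unit_jitter = 0.05) {
  stopifnot(inherits(spec, "spike_pop_spec"))
  with_local_seed(seed, {
    pop <- expand_units(spec$classes)
    n_units <- nrow(pop)
    jit <- function(x) x * exp(stats::rnorm(length(x), sd = unit_jitter))
    pop$rate_hz <- jit(pop$rate_hz)
    pop$trough_to_peak_ms <- jit(pop$trough_to_peak_ms)
    pop$half_width_ms <- jit(pop$half_width_ms)
    pop$peak_valley_ratio <- jit(pop$peak_valley_ratio)
    units <- vector("list", n_units)
    for (u in seq_len(n_units)) {
      ts <- renewal_train(pop$rate_hz[u], spec$refractory_ms / 1000,
                          spec$duration_s)
      tmpl <- spike_template(pop$trough_to_peak_ms[u], pop$half_width_ms[u],
                             pop$peak_valley_ratio[u],
                             depth = pop$amplitude_sd[u] * spec$noise_sd,
                             fs = spec$fs)
      wf <- matrix(stats::rnorm(length(ts) * length(tmpl),
                                sd = spec$noise_sd),
                   nrow = length(ts))
      wf <- sweep(wf, 2, tmpl, `+`)
      units[[u]] <- spike_unit(timestamps = ts, waveforms = wf,
                               fs = spec$fs,
                               recording_duration_s = spec$duration_s,
                               unit_id = paste0("u", u))
    }
    pop$unit_id <- paste0("u", seq_len(n_units))
    list(units = units, truth = pop)
  })
}

# Photometry --------------------------------------------------------------

#' Specification for a synthetic two-channel photometry recording
#'
#' The 470 nm channel carries a photobleaching baseline, calcium transients,
#' and a shared motion artifact; the 410 nm isosbestic channel carries the
#' bleaching baseline and the same motion artifact but no calcium signal.
#' Transients are double-exponential (rise then decay), normalized so a
#' transient of `amplitude` a reaches a peak of `a * f0_470` above baseline.
#'
#' @param fs Sampling rate, Hz (default 30, typical of demodulated
#'   photometry streams).
#' @param duration_s Recording length, seconds.
#' @param f0_470,f0_410 Baseline fluorescence of each channel (arbitrary
#'   units, positive).
#' @param bleach_tau_s Photobleaching exponential time constant; `Inf`
#'   disables bleaching.
#' @param bleach_frac Fraction of baseline lost as the bleaching exponential
#'   completes.
#' @param transients Data frame with columns `t_s`, `amplitude` (fraction of
#'   F0), `rise_s`, `decay_s`.
#' @param motion_amp SD of the shared additive motion artifact, as a
#'   fraction of `f0_470` (0 disables).
#' @param noise_sd Per-channel white measurement noise, as a fraction of the
#'   channel baseline.
#' @param event_tags Behavioral event times, seconds; each must be at least
#'   120 s after the start so a 2-minute baseline exists.
#' @return A `photo_spec` object.
#' @export
photo_spec <- function(fs = 30, duration_s = 600, f0_470 = 100,
                       f0_410 = 60, bleach_tau_s = Inf, bleach_frac = 0.2,
                       transients = NULL, motion_amp = 0, noise_sd = 0,
                       event_tags = numeric()) {
  if (f0_470 <= 0 || f0_410 <= 0) stop("baselines must be positive",
                                       call. = FALSE)
  if (length(event_tags) && any(event_tags < 120)) {
    stop("event tags must be at least 120 s after the recording start",
         call. = FALSE)
  }
  if (is.null(transients)) {
    transients <- tibble::tibble(t_s = numeric(), amplitude = numeric(),
                                 rise_s = numeric(), decay_s = numeric())
  }
  transients <- tibble::as_tibble(transients)
  structure(as.list(environment()), class = "photo_spec")
}

# Peak-normalized double-exponential transient kernel evaluated at times
# since onset (vector, >= 0).
transient_kernel <- function(dt, rise_s, decay_s) {
  k <- (1 - exp(-dt / rise_s)) * exp(-dt / decay_s)
  t_pk <- rise_s * log(1 + decay_s / rise_s)
  pk <- (1 - exp(-t_pk / rise_s)) * exp(-t_pk / decay_s)
  k / pk
}

#' Generate a synthetic photometry recording with ground truth
#'
#' @param spec A [photo_spec()].
#' @param seed Integer seed.
#' @return A list with `recording` (a [photometry_recording()]) and `truth`
#'   (the transient table plus the clean calcium component).
#' @export
gen_photometry <- function(spec, seed) {
  stopifnot(inherits(spec, "photo_spec"))
  with_local_seed(seed, {
    n <- round(spec$duration_s * spec$fs)
    t <- (seq_len(n) - 1) / spec$fs
    bleach <- if (is.finite(spec$bleach_tau_s)) {
      1 - spec$bleach_frac * (1 - exp(-t / spec$bleach_tau_s))
    } else rep(1, n)
    ca <- numeric(n)
    for (i in seq_len(nrow(spec$transients))) {
      tr <- spec$transients[i, ]
      on <- t >= tr$t_s
      ca[on] <- ca[on] + tr$amplitude * spec$f0_470 *
        transient_kernel(t[on] - tr$t_s, tr$rise_s, tr$decay_s)
    }
    motion <- if (spec$motion_amp > 0) {
      raw <- colored_noise(n, beta = 2, sd = spec$motion_amp * spec$f0_470,
                           fs = spec$fs)
      raw
    } else numeric(n)
    noise470 <- if (spec$noise_sd > 0) {
      stats::rnorm(n, sd = spec$noise_sd * spec$f0_470)
    } else numeric(n)
    noise410 <- if (spec$noise_sd > 0) {
      stats::rnorm(n, sd = spec$noise_sd * spec$f0_410)
    } else numeric(n)
    f470 <- spec$f0_470 * bleach + ca + motion + noise470
    f410 <- spec$f0_410 * bleach + motion + noise410
    rec <- photometry_recording(f470 = f470, f410 = f410, fs = spec$fs,
                                event_tags = spec$event_tags)
    list(recording = rec,
         truth = list(transients = spec$transients, calcium = ca,
                      motion = motion))
  })
}
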