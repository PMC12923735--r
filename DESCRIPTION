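Package: neuropac
Title: Hippocampal Oscillation, Spike, and Fiber-Photometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in vivo hippocampal electrophysiology and fiber
    photometry: band-limited power spectra (Welch/Hann), theta-gamma
    phase-amplitude coupling via the mean-vector-length modulation index,
    detection of epileptiform discharges under energy, duration and channel
    contiguity criteria, ripple (140-200 Hz) and fast-ripple (200-500 Hz)
    event detection, spike-unit quality control and fast-spiking versus
    regular-spiking classification with a Gaussian mixture model, and
    delta-F/F event-aligned photometry with an isosbestic control channel.
    Includes seeded synthetic-data generators for local field potentials,
    spike-band traces, and two-channel photometry so every analysis stage
    is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
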