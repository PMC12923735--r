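---
title: "Methods: oscillation, coupling, event, spike, and photometry analysis in neuropac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillation, coupling, event, spike, and photometry analysis in neuropac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropac)
```

neuropac analyzes in vivo hippocampal recordings of three kinds: multi-channel
local field potentials (LFP, 1 kHz class), spike-band traces (40 kHz class),
and two-channel fiber photometry. This vignette explains the models and
estimators behind each stage, the parameters that matter, what the synthetic
generators emulate, and the numerical and design choices a maintainer would
want spelled out.

## Signal model and containers

A recording is a `continuous_signal`: a samples-by-channels matrix plus
sampling rate, start time, units, and a channel-contiguity *geometry* — a
list of neighbor pairs describing which electrodes are physically adjacent
(for a 4 x 2 wire array read out shank by shank, a linear chain is the
default). The geometry is an explicit input because the epileptiform
detector's channel-contiguity criterion must not guess the electrode layout.

Recordings are processed as sequential 5-minute segments
(`segment_signal()`), the storage convention for hour-long sessions. A
trailing shorter segment is kept and flagged, and every per-segment rate is
normalized by the segment's true duration rather than the nominal one.

## Band-limited filtering

All band-limited operations use a 4th-order Butterworth filter applied
forward and backward (zero phase, so detected event times are not shifted;
the magnitude response is applied twice). The filter runs as a cascade of
second-order sections rather than one transfer function: for a band such as
theta (3–8 Hz) at 1 kHz the poles cluster near \(z = 1\), and a single
8th-order polynomial amplifies roundoff to the \(10^{-3}\) level, while
biquads keep linearity at the \(10^{-13}\) level. Passband ripple is below
1 dB and attenuation one octave outside the band exceeds 20 dB.

Band presets follow the conventions of hippocampal work: theta 3–8 Hz for
spectral summaries and 4–12 Hz (`theta_wide`) for filtered-trace display and
phase extraction; low gamma 30–50 Hz, high gamma 50–90 Hz, broad gamma
30–80 Hz; ripple 140–200 Hz; fast ripple 200–500 Hz. Both theta presets ship
because the two conventions coexist in practice; phase extraction defaults
to the wide preset and is configurable.

## Power spectra

`welch_psd()` averages Hann-windowed, mean-removed segments with 25%
overlap. The window length is `2 * (n_freq_values - 1)` samples, so the
default 1024 one-sided frequency values correspond to a 2046-sample window.
The estimate is a one-sided density in units²/Hz normalized so that its
integral over frequency equals the signal variance (Parseval, window-power
corrected); the tests check this within 5% for tones and 10% for broadband
noise. Absolute units of other spectral software are often proprietary;
because comparative claims (ratios across bands or conditions) are invariant
to a global scale, the variance normalization is the defensible choice.
Band powers are trapezoidal integrals over `[f_lo, f_hi]` (less sensitive to
edge-bin placement than bin summation) and are exactly additive over
disjoint bands. A whole recording can be estimated per 5-minute segment and
averaged (`per_segment = 300`) or as one Welch block; both are exposed, and
segment-averaging is the default convention in `run_pipeline()` only when
requested.

## Phase–amplitude coupling

The coupling statistic is the mean-vector-length modulation index
\[
\mathrm{MIn} = \Big| \tfrac{1}{n} \sum_{t=1}^{n} A_t \, e^{i\theta_t} \Big|,
\]
with \(\theta_t\) the instantaneous phase of the low (theta) band and
\(A_t\) the instantaneous amplitude of the high (gamma) band, both obtained
from the analytic signal (Hilbert transform) of the zero-phase band-passed
trace — the field-standard realization of this estimator family. One second
is trimmed from each end of the series to discard filter transients
(`edge_s`).

Raw MIn carries the amplitude's units, so recordings with larger gamma
amplitude get larger MIn at equal coupling. The dimensionless
`min_normalized = MIn / mean(A_t)` (in [0, 1] by the triangle inequality) is
reported alongside for cross-condition comparisons. A minimum of ten
low-band cycles is recommended; shorter series warn.

For the synthetic generator's gamma envelope
\(A(t) \propto 1 + m\cos(\theta - \phi)\), the noiseless normalized index is
\(m/2\); background noise dilutes it, but monotonicity in \(m\) is preserved
and verified (Spearman \(\rho = 1\) across \(m \in \{0, .25, .5, .75, 1\}\),
five seeds each, 120-s recordings).

`comodulogram()` scans a grid of band pairs; its optional null level uses
circular time-shifts of the amplitude series (minimum 1 s, seeded), which
preserve the amplitude autocorrelation while destroying the phase
relationship.

## Oscillatory event detection

**Epileptiform discharges** are detected by conjunctive criteria: energy of
the >100 Hz component rising more than 4 baseline SDs, duration at most
4 s, and co-occurrence on at least 5 channels contiguous under the
geometry — the literal "more than 4" reading; the inclusive alternative is
one argument away (`min_channels_contig = 4`). Per channel the signal is
high-pass filtered at 100 Hz and a 20-ms RMS energy envelope is thresholded;
baseline mean and SD are computed on the envelope (the criterion's SD is
taken on energy, not the raw trace) over the whole recording with a second
pass that excludes first-pass detections, or over a user-stated interval
(with a warning and re-computation if that interval itself contains
supra-threshold activity). Supra-threshold runs overlapping in time across
channels merge into one candidate whose channel set is the union.
Sharp-wave-ripple-type events (dominant frequency above 200 Hz) recorded
during freely-moving epochs are additionally counted as epileptiform; this
relabeling is an explicit step (`promote_swr_events()`) applied to
band-event detections rather than a hidden branch of the multichannel
detector. "Bursting firing" within discharges has no quantitative
definition and is not tested.

**Ripples (140–200 Hz) and fast ripples (200–500 Hz)** are detected on the
band-passed analytic-signal envelope, Gaussian-smoothed with \(\sigma =
4\) ms. The detection thresholds refer to the *unsmoothed* envelope's mean
and SD; smoothing only stabilizes run boundaries. An event requires the
envelope to exceed mean + 3 SD for at least half the minimum duration
(ripple 20 ms, fast ripple 10 ms); event edges then extend outward to the
mean + 2 SD crossing (the dual-threshold convention, which stops brief
in-event envelope dips from splitting an event), and events closer than
10 ms merge. Per event the peak envelope amplitude and the dominant
intra-event frequency are reported; the frequency is the band-limited
trace's mean inter-peak interval between positive local maxima (intervals
more than twice the median are treated as missed cycles and excluded),
giving sub-sample resolution where a median interval would quantize to
whole samples.

Calibration on twenty seeded noise-only runs at these defaults measures a
false-detection rate of about 3 events/min in the ripple band and about 0
in the fast-ripple band; raising `envelope_sd_mult` to 3.5 brings the
ripple band under 2/min at a small sensitivity cost. On injected events
whose envelope peaks 5 SDs above the band mean, measured sensitivity is
0.98–1.00, precision 0.97–1.00, onset error under 5 ms, and intra-event
frequency within 2 Hz of the carrier (10 seeds, 20 events each).

Because "ripple frequency" is ambiguous between occurrence rate and
intra-event oscillation frequency, summaries report both
(`event_rate_per_min` and `mean_intra_freq_hz`) and never guess. Epochs
overlapping epileptiform discharges are excluded from physiological ripple
summaries by default in the pipeline (`exclude_overlapping()`); the helper
is exported so the choice is visible and reversible.

A note on sampling rates: an acquisition chain that low-passes field
potentials at 250 Hz before 1 kHz storage cannot carry 200–500 Hz content;
the toolkit therefore requires `fs >= 2 * f_hi` for any band and the
synthetic fast-ripple fixtures run at 2 kHz.

## Spike analysis

Spikes are detected as negative crossings of 3 noise SDs, with the noise SD
estimated by the median absolute deviation scaled to the Gaussian SD
(robust to spike contamination), trough-aligned in a −0.5/+1.5 ms window,
with a 1-ms dead time. On Gaussian noise, a 3-SD threshold at 40 kHz
necessarily yields on the order of tens of crossings per second (the Rice
crossing rate); the tests document the measured noise-only rate against
that analytic value rather than pretending the threshold suppresses it.
Detections coincident within 0.5 ms on 6 or more of 8 channels are
electrical artifacts and are invalidated; both parameters are defaults, not
reported values. Full spike *sorting* (PCA clustering) is intentionally out
of scope: the package accepts externally sorted units and uses a
single-template-per-channel convention for synthetic data, because the
bespoke analysis content is thresholding, QC, and classification.

Unit QC operationalizes the absolute refractory period as a violation
fraction: a unit is kept when at most 0.5% of inter-spike intervals fall
below 1 ms (boundary inclusive) and it is not an artifact. Waveform
features on the mean waveform are: trough-to-peak time, width of the trough
at half depth (linear interpolation between samples), peak-to-valley
amplitude ratio, and trough-to-peak slope.

Classification into fast-spiking (FS, putative PV+ interneurons) and
regular-spiking (RS, putative pyramidal) units fits a two-component
full-covariance Gaussian mixture to standardized (log firing rate,
peak-valley ratio, half-height width). The fit uses mclust's deterministic
model-based hierarchical initialization, so results are exactly
reproducible; a singular fit falls back to diagonal covariance with a
warning, and a population of indistinguishable units is reported as one
class at responsibility 0.5 and flagged low-confidence rather than split
arbitrarily. The component with the shorter mean width is labelled FS. On
the two-population synthetic (FS 20 Hz / 0.2 ms, RS 2 Hz / 0.5 ms, 20 units
each, 5% parameter jitter), accuracy is 100% across ten seeds.

## Fiber photometry

The 470-nm channel reports calcium-sensitive GCaMP6s fluorescence; the
410-nm isosbestic channel is calcium-insensitive and serves as a motion
control. For each behavioral event tag, \(\Delta F/F = (F - F_0)/F_0\) with
\(F_0\) the channel's mean over the two minutes preceding the tag — a
per-tag local baseline, which also absorbs slow photobleaching without any
global detrending. Tags earlier than 120 s cannot have a baseline and are
rejected at construction. \(\Delta F/F\) is exactly invariant to any common
gain on the channel.

Event-aligned windows (default −2 to +5 s) are interpolated onto a common
grid at the native sampling rate and summarized as a per-event matrix
(heatmap), mean curve, and SEM. The area under the curve is a trapezoidal
integral, by default over the post-event window 0 to +5 s (whether the
convention includes the pre-event seconds is genuinely ambiguous; the
window is an argument). The isosbestic check reports the 470/410
\(\Delta F/F\) correlation per event and emits a motion-corrected trace
(470 minus a least-squares linear transform of 410 fitted on the pre-event
samples) *alongside* the raw \(\Delta F/F\) — the raw per-channel formula
is the primary output, and no correction is ever applied silently, because
the upstream artifact-correction procedure this mirrors is unstated.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage can be verified against ground truth
without animal data; all are seeded (R's Mersenne–Twister, local RNG state)
and return complete truth tables.

* `gen_lfp()`: 1/f\(^\beta\) background (spectrally shaped white noise with
  exact exponent control; slope −1 ± 0.2 verified over 1–100 Hz), a theta
  sinusoid, gamma whose envelope is \(\propto 1 + m\cos(\theta-\phi)\), and
  injected carrier bursts under a raised-cosine envelope whose ramps span
  5% of the event per side — short enough that detected durations match
  nominal within 0.1 s, long enough to avoid edge ringing. Default
  amplitudes are microvolt-scale (theta 50, gamma 20, noise SD 15 µV) with
  half the background variance shared across the 8 channels. Event
  amplitudes are stated in multiples of the background SD; tests that need
  "k envelope SDs in band" calibrate that multiplier on a noise-only run.
* `gen_spikes()` / `gen_spike_units()`: renewal trains (exponential ISIs
  plus a hard dead time, preserving the nominal rate), biphasic templates —
  a negative Gaussian trough whose FWHM is the half-width parameter and a
  compact-support raised-cosine positive lobe, with lobe amplitudes solved
  so trough depth and peak ratio are exact despite tail overlap — scaled
  into white noise of known SD. The continuous form places one unit per
  channel at 40 kHz; the population form builds unit objects directly
  (timestamps plus noisy waveforms) for classifier studies where simulating
  forty 40-kHz channels would serve no purpose.
* `gen_photometry()`: shared exponential bleaching, double-exponential
  calcium transients on the 470 channel only, and a shared additive motion
  artifact in both channels (Brownian-spectrum noise), plus white
  measurement noise.

What passing tests on these data do **not** show: robustness to real
electrode drift, chewing/grooming artifacts, non-Gaussian noise, overlapping
spike waveforms from nearby units, hemodynamic or wavelength-dependent
photometry artifacts, or behavioral covariates. The generators are
statistical mirrors of the analysis assumptions, not biophysical
simulations.

## Pipeline, reproducibility, and problem sizes

`run_pipeline()` executes simulate → spectra → coupling → events → spikes →
photometry from one validated configuration (unknown keys are rejected).
Every stage draws its seed from the master seed through a documented rule
(`child_seed()`: `seed * 7919 + sum of the stage name's character codes,
mod 2^31 - 1`), so stages are independently reproducible and two runs of
the same configuration have identical content fingerprints
(`report_fingerprint()` hashes the report minus its timestamp).
`compare_conditions()` reports descriptive differences and ratios only —
group inferential statistics are out of scope — and reports ratios with a
zero denominator as absent, never infinite.

The default verification sizes — 60–120 s recordings, 20 injected events
per run, 5–10 seeds per property, 40-unit classifier populations — were
chosen as the smallest sizes at which the binomial/Poisson noise of the
measured rates is clearly below the contract margins; the full suite and
the acceptance script each complete in about a minute on one CPU.

## Known limitations

* NWB/broker formats are not read; I/O covers delimited text and raw
  float32 with a JSON sidecar.
* The epileptiform detector assumes the geometry faithfully encodes
  physical adjacency; with a wrong geometry the contiguity criterion is
  meaningless.
* Raw MIn values are not comparable across hardware gains; use the
  normalized index for cross-condition claims.
* The ripple-band false-detection rate at the default 3-SD threshold is
  about 3 events/min on noise; studies needing a stricter floor should
  raise `envelope_sd_mult` and re-calibrate sensitivity.
* The spike path classifies externally sorted or synthetically assigned
  units; it does not resolve overlapping units on one channel.
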