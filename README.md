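# neuropac

Analysis of in vivo hippocampal electrophysiology and fiber photometry in
R: band-limited power spectra, theta–gamma phase–amplitude coupling,
epileptiform / ripple / fast-ripple event detection, spike-unit quality
control and cell-type classification, and event-aligned ΔF/F photometry —
together with seeded synthetic-data generators so every stage is verifiable
against known ground truth.

## Who this is for

Labs recording local field potentials (LFP), extracellular spikes, and
GCaMP photometry in rodent models of network dysfunction — epilepsy,
interneuronopathies, neurodegeneration — who need the standard quantitative
readouts of hippocampal circuit state as tested, scriptable, reproducible
functions rather than point-and-click software.

## What it computes

**Phase–amplitude coupling.** The strength with which the theta phase
θ_t modulates the gamma amplitude A_t is quantified by the
mean-vector-length modulation index

    MIn = | n⁻¹ Σ_{t=1..n} A_t · e^{iθ_t} |

with phase and amplitude taken from the analytic signal of the zero-phase
band-passed trace. The dimensionless `min_normalized = MIn / mean(A_t)` ∈
[0, 1] is reported alongside for cross-condition comparison, and
`comodulogram()` scans band-pair grids.

**Spectra.** Welch/Hann power spectral density (1024 one-sided frequency
values, 25% window overlap, variance-normalized) with trapezoidal band
powers over theta (3–8 Hz), low gamma (30–50 Hz), high gamma (50–90 Hz) and
any custom band; spectrograms for time-frequency views.

**Events.** Epileptiform discharges are detected by conjunctive criteria —
energy of the >100 Hz component above 4 baseline SDs, duration ≤ 4 s, on
≥ 5 contiguous channels of the electrode array — and ripples (140–200 Hz)
and fast ripples (200–500 Hz) by a dual-threshold analytic-envelope
detector reporting occurrence rate, peak amplitude, duration, and
intra-event oscillation frequency.

**Spikes.** Threshold detection (3 robust SDs), cross-channel artifact
invalidation, refractory-period QC (≤ 0.5% of inter-spike intervals below
1 ms), waveform features (trough-to-peak, half-height width, peak-valley
ratio, slope), and fast-spiking vs regular-spiking classification with a
two-component Gaussian mixture.

**Photometry.** Per-event ΔF/F = (F − F₀)/F₀ with a 2-minute pre-event
baseline on the 470-nm calcium channel and the 410-nm isosbestic control,
event-aligned mean ± SEM curves, per-event heatmap matrices, trapezoidal
AUC, and an explicit (never silent) isosbestic motion-correction.

All result types are tibbles or carry `tidy()`/`glance()` methods and
`autoplot()` ggplot2 visualizations, so results compose with dplyr pipes.

## Worked example

Simulate two minutes of 8-channel LFP with strong theta–gamma coupling and
one injected epileptiform burst, then run the main analyses:

```r
library(neuropac)

sim <- gen_lfp(lfp_spec(duration_s = 120, coupling_depth = 0.8, events = list(
  event_spec("epileptiform", t_on = 45, duration_s = 2, carrier_hz = 150,
             amplitude = 6, channels = 1:6))), seed = 1)
sim$signal
#> <continuous_signal> 8 channel(s) x 120000 samples @ 1000 Hz (120.000 s), units uV

p <- welch_psd(sim$signal)
band_power(p, band_presets()[c("theta", "low_gamma", "high_gamma")]) |>
  dplyr::group_by(band) |> dplyr::summarise(mean_power = mean(power))
#> # A tibble: 3 × 2
#>   band       mean_power
#>   <chr>           <dbl>
#> 1 high_gamma       11.7
#> 2 low_gamma        92.4
#> 3 theta          1267.

modulation_index(extract_pac_series(sim$signal, channel = 1))
#> <pac_result> MIn = 3.68899 (normalized 0.2956), n = 118000

ev <- detect_epileptiform(sim$signal)
ev[, c("kind", "t_on", "t_off", "duration_s", "n_channels_contig", "intra_freq_hz")]
#> # A tibble: 1 × 6
#>   kind          t_on t_off duration_s n_channels_contig intra_freq_hz
#>   <chr>        <dbl> <dbl>      <dbl>             <int>         <dbl>
#> 1 epileptiform  45.0  47.0       1.96                 7          151.

summarize_events(ev, signal_duration(sim$signal))$overall
#> # A tibble: 1 × 5
#>   n_events event_rate_per_min mean_intra_freq_hz mean_peak_amplitude
#>      <int>              <dbl>              <dbl>               <dbl>
#> 1        1                0.5               151.                69.2
```

Reading the output: theta power dominates the spectrum as expected for a
theta-paced recording (the injected 50 µV theta sinusoid carries
50²/2 ≈ 1250 µV² of power); the normalized modulation index of 0.30
reflects the generated coupling depth of 0.8 diluted by background noise
(a noiseless recording at depth m gives m/2 = 0.40); and the detector
recovers the one injected burst — its 2-s duration, its ~150 Hz carrier,
and a contiguous 7-channel footprint (the 6 injected channels plus one
neighbor crossing threshold), at 0.5 events/min over the 2-minute
recording.

The full pipeline runs from one seeded config —
`run_pipeline(run_config(seed = 1, ...))` — and `compare_conditions()`
contrasts two runs (e.g. a disease-like parameterization with injected
discharges against a control-like one) as a table of descriptive
differences and ratios.

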