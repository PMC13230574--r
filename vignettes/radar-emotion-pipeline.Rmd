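---
title: "Methods: FMCW radar vital signs and the multimodal emotion baseline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FMCW radar vital signs and the multimodal emotion baseline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emowave)
```

This vignette is the package's account of the science it implements: the
radar signal model and vital-sign extraction chain, the physiological
conditioning chains, the feature definitions, the rating statistics and the
classification baseline, together with the numerical choices, defaults and
known limitations. The companion scripts under `analysis/` run the whole
workflow on a synthetic cohort; `scripts/acceptance.R` recomputes the
headline numbers.

## The sensing problem

A frequency-modulated continuous-wave (FMCW) radar transmits linear
frequency sweeps ("chirps") and mixes each echo with the transmitted sweep,
producing an intermediate-frequency (IF) beat tone. Two properties of that
tone carry all the information used here:

* its **frequency** `f_IF = S * 2R / c` encodes the reflector's range `R`
  (slope `S`, speed of light `c`);
* its **phase** `phi = 4 * pi * R / lambda` encodes sub-wavelength radial
  motion at 60 GHz (`lambda` = 5 mm), so millimeter chest-wall displacement
  from breathing (~1-5 mm) and sub-millimeter cardiac motion (~0.05-0.3 mm)
  modulate the phase by radians and fractions of a radian respectively.

The default `radar_config()` is the study device: 60 GHz start frequency,
3790.97 MHz sweep at 66.590 MHz/us, 256 ADC samples per chirp at 5.12 MHz,
a 3 Tx x 4 Rx TDM virtual array (12 channels), 100 Hz frame rate. The range
bin size follows from the bandwidth actually swept during ADC capture,
`delta_r = c / (2 * S * N / f_s)` = 0.0451 m. Throughout the package
`c = 3e8` m/s — the radar-engineering convention, and the one under which
the derived quantities agree with the device datasheet to their printed
precision (with exact `c` the bin size would print as 0.0450 m).

## Synthetic scenes

`simulate_adc_cube()` renders a scene — one breathing target plus static
clutter plus complex receiver noise — into the raw `channels x fast-time x
slow-time` ADC cube, under two standard approximations:

* **Stop-and-hop**: the chest range is evaluated once per chirp. Chest
  velocity times chirp duration is ~10^-7 m, eight orders below the range
  resolution.
* **Displacement-to-phase linearization**: each reflector's beat frequency
  is fixed at its baseline range while the phase term uses the
  instantaneous range. A mm-scale displacement moves the beat tone by
  ~1 kHz against a 20 kHz bin — unresolvable — but would add a
  slow-time-varying spectral-leakage phase of ~3% of the main term to every
  bin, which has no physical counterpart sharper than the binning itself.
  Freezing the beat frequency keeps the simulated bin phase exactly
  `4*pi*R(t)/lambda + const`, which is what makes the sub-micro-radian
  phase-fidelity checks meaningful.

The chest model is a sum of sinusoids: respiration (rate in (0, 0.5] Hz,
default 0.25 Hz at 3 mm, one 20% second harmonic), heartbeat (0.5-3 Hz,
default 1.2 Hz at 0.1 mm), optional ramp artifacts, and **onset phases**
for both components. The onset phases matter: a recording never starts at a
fixed point of either physiological cycle, and fixing both phases to zero
creates measure-zero coincidences (e.g. a heart rate exactly four times the
respiration rate stays phase-locked to respiration harmonics for the whole
record). Cohort-level simulations therefore draw onset phases uniformly.

Channels carry identical target returns with independent complex Gaussian
noise (`noise_sd` = 1 per quadrature sample relative to unit target
amplitude — a conservative raw-ADC noise floor; the study reports no
quantitative noise characterization, so this is a documented choice, not a
claim about the recording hardware). Clutter is strictly static and the target
amplitude constant over slow time; antenna patterns, multipath and TDM
phase migration are out of scope.

## Vital-sign extraction

`extract_vital_sign()` implements the chain:

1. **Range FFT** per channel along fast time (rectangular window, no
   zero-padding); bin `b` (0-based) spans `[b, b+1) * delta_r`.
2. **MTI mean cancellation**: each range bin's complex slow-time mean is
   subtracted, removing static clutter exactly while leaving the slow-time
   variance of moving returns untouched.
3. **Multi-bin selection**: the K = 5 bins with the largest mean slow-time
   magnitude inside a 0.3-1.5 m search window (the seating span 0.6-0.9 m
   with margin; the window is a parameter and can be widened to the full
   span). Ties break toward the nearer bin.
4. **Phase fusion**: per selected bin the complex argument of the slow-time
   series is unwrapped (+-2*pi corrections so successive steps lie in
   (-pi, pi]) and the unwrapped phases are combined with weights
   proportional to the bins' mean amplitudes (weights sum to 1; bins with
   zero-magnitude samples are dropped and the weights renormalized).
5. **Channel averaging** of the fused phases, then a **first difference**
   (removing low-frequency drift) — the *vital sign*.
6. **Band-pass filtering**: respiration 0.1-0.5 Hz (4th order), heartbeat
   1.0-1.8 Hz (6th order), both Butterworth and both applied
   forward-backward. The quoted orders refer to the designed prototype;
   the bidirectional pass squares the magnitude response and cancels phase
   distortion, which would otherwise corrupt beat timing.

Two numerical points deserve emphasis:

* **Filter realization.** At a 100 Hz slow-time rate the heartbeat band is
  1% of the sampling rate; a transfer-function Butterworth of order 6 is
  numerically unstable in double precision (rounded poles leave the unit
  circle). Filters are therefore designed in zero-pole-gain form and
  applied as a cascade of biquad sections, each pass running over an
  odd-symmetric extension of the record with the section started in steady
  state, so constants pass through exactly and edge transients stay in the
  discarded padding.
* **MTI phase distortion.** Subtracting a bin's complex mean `m` perturbs
  the argument of the residual phasor: `arg(e^{i*theta} - m)` equals
  `theta` only up to terms of order `|m|`, which contain harmonics and
  intermodulation products of the respiration and heartbeat lines. For
  realistic breathing excursions (several radians) `|m|` is small but not
  negligible (~0.1-0.3), and the distortion products in the 1.0-1.8 Hz band
  are a few percent of the respiration line. This is intrinsic to
  mean-cancellation-then-angle and is kept exactly as the method defines
  it. Its one practical consequence is described under *Limitations*.

`phase_to_displacement()` converts phase to displacement via
`delta_d = lambda * delta_phi / (4 * pi)`.

## PPG and GSR conditioning

`process_ppg()`: zero-phase 4th-order Butterworth band-pass 0.6-5 Hz,
subtraction of the least-squares straight-line fit, then a centered 20
sample (0.1 s) moving average with edge truncation (the window shrinks at
the boundaries rather than padding; the boundaries lie outside the analysis
tail anyway). `process_gsr()`: conductance conversion `uS = 1000 / kOhm`
(so the sensor's 100 kOhm limit maps to 10 uS; the conversion is an exact
involution) followed by a zero-phase 3rd-order low-pass at 1 Hz.

The PPG generator is a fixed two-lobe beat template (systolic peak +
dicrotic bump, Gaussian lobes scaled to the beat interval) with Gaussian
interval jitter; morphology is fixed because nothing downstream uses it
beyond band content. The GSR generator is a tonic conductance level plus
bi-exponential phasic responses, inverted to resistance and clipped to the
sensor's 100-2500 kOhm range.

## Signal-quality metrics

`snr_db()` splits a record at a cutoff (15 Hz for PPG, 1 Hz for GSR) with a
matched pair of zero-phase 3rd-order Butterworth low-/high-pass filters and
returns `10*log10` of the mean-square ratio. The PPG boundary's filter
order is not specified by the source description; the GSR order (3rd) is
used for both and documented here. `dominant_frequency()` reads the peak of
a zero-padded magnitude spectrum (grid <= 0.005 Hz) inside a band — default
0.8-2.0 Hz for heart rate (the 1.0-1.8 Hz design band with margin) and
0.1-0.5 Hz for respiration — over the whole trial. `hr_agreement()`
summarizes per-trial absolute errors between radar- and PPG-derived rates
as MAE, median, SD and mean relative error.

## Features

Features are computed over the **final 60 s** of each trial in twelve
non-overlapping 5 s windows (`window_spec()`, `window_slices()`). Schemas
are fixed and length-checked: 32 mmWave, 28 PPG, 24 GSR features
(`feature_schema()`).

* Statistical block: mean, SD, mean |first difference|, mean |second
  difference| of the signal and of its variance-normalized copy.
* `nsi()`: SD of the 10 segment means of the variance-normalized signal
  (the convention in the affective-computing literature; no formula is
  given by the source, so this is a documented choice). Constant signals
  return 0.
* `hfd()`: Higuchi's curve-length regression with `kmax = 10` (1 for a
  line, ->2 for white noise).
* PSD bands: mean of a zero-padded rectangular-window periodogram over
  0-0.1/0.1-0.2/0.2-0.3/0.3-0.4 Hz for respiration and 1.0-1.3/1.3-1.6/
  1.6-1.8 Hz for heartbeat (the "0-0.l Hz" band in the source's feature
  table is read as 0-0.1 Hz). The padding brings the frequency grid to
  <= 0.025 Hz so 0.1 Hz-wide bands are populated even for 5 s windows.
* `hht_features()`: in-package empirical mode decomposition (cubic-spline
  envelopes on mirror-extended extrema, Cauchy-type sifting criterion 0.2)
  followed by the FFT analytic signal; per IMF 1-4 the mean instantaneous
  frequency and amplitude, with 5% edge trimming against Hilbert edge
  artifacts. Missing IMFs are zero-filled and flagged.
* HRV (`hrv_features()` on `detect_beats()` output): meanNN, medianNN,
  SDNN, RMSSD, pNN50 (> 50 ms), meanRate, sdRate, HRVTi (interval count /
  modal count of a 1/128 s-bin histogram) and SD1, computed from the
  Poincare perpendicular distances `(NN[i+1]-NN[i])/sqrt(2)` so that
  SD1 = RMSSD/sqrt(2) holds as an exact identity.

Beat detection replaces the external dynamic-programming template-matching
segmentation with prominence-thresholded local maxima (adaptive threshold
`median + 0.3 * (max - median)`, greedy 0.45 s refractory period) behind a
narrow interface, so a different detector can be substituted without
touching the features. Because a 5 s window holds only ~5-9 beats, windows
with fewer than 3 NN intervals carry the trial-level HRV (computed over the
full 60 s tail) forward, flagged in the matrix's `hrv_fallback` attribute —
the source does not address this degeneracy, and zero-variance HRV from 2-3
intervals would be noise.

## Rating statistics

`cv_summary()` computes per-clip coefficients of variation (sample SD /
mean) per scale and their mean/SD across the 18 clips, from raw ratings or
from a per-clip moment summary; the shipped `clip_rating_summary()` table
reproduces mean CVs of 0.26 (valence), 0.32 (arousal), 0.29 (dominance).
`spearman_rho()` is the Pearson correlation of average ranks — the correct
tie treatment for discrete 1-9 scales — with a two-sided t-based p-value
helper. `quadrant()` maps (valence, arousal) to LALV/LAHV/HALV/HAHV with
center-valued coordinates assigned to the low half (display convention
only; threshold-5 trials never reach the classifier). `binarize_labels()`
labels ratings below 5 "low", above 5 "high", and excludes exact 5s;
`class_distribution()` counts window-level samples (12 per labeled trial).

## Classification baseline

Per participant and scale: `split_by_trial()` keeps the first 75% of each
labeled trial's windows (12 -> 9/3) for training; `zscore_fit_apply()`
standardizes with training-set statistics only (constant features map to 0,
flagged); `grid_search_svm()` evaluates all 66 (C, gamma) pairs —
`C = 10^(-5..5)`, `gamma = 10^(-4..1)`, the unique geometric sequences with
the stated endpoints and counts — by stratified 5-fold CV accuracy on the
training set with seeded fold assignment, refitting the winner (ties to the
first pair in grid order); `evaluate()` reports accuracy, balanced accuracy
(mean of per-class recalls), the high-class F1 with macro-F1 alongside, and
the confusion counts. CV-based selection is a choice: the source states
grid search without a selection protocol, and selecting on the test set
would leak; absolute accuracies may shift accordingly.

## What the synthetic data does and does not show

The generators emulate the statistical structure the pipeline assumes:
phase-modulated multi-channel radar returns with static clutter and
receiver noise, quasi-periodic band-limited PPG, slow tonic/phasic GSR, and
integer SAM ratings from per-clip normal populations. Passing tests
demonstrate that the implementation recovers known simulation parameters
and satisfies the method's internal identities. They do not demonstrate
performance on real recordings: real chest echoes contain posture drift,
RCS fluctuation and body-motion artifacts; real PPG morphology and HRV are
not interval-jittered templates; real ratings are not independent normals.
Dataset-level quantities (heart-rate MAE of 2.76 bpm against PPG, PPG SNR
of ~48-53 dB, GSR SNR of ~25-43 dB, accuracies of 60-70%) are properties of
the deposited recordings and can only be checked against them; the same
procedures run here on synthetic trials, where clean simulations yield
sub-bpm agreement.

## Problem sizes

The shipped analyses and checks use: 60-70 s trials at the full device
configuration (12 channels, 256 samples, 100 Hz) for end-to-end runs;
a 16-cell rate grid (respiration 0.15-0.45 Hz x heart 1.0-1.7 Hz) with two
seeded repetitions for recovery-rate estimation; a 2-participant x 3-clip
raw cohort plus a 15-participant rating cohort in the analysis scripts; and
reduced 64-sample/2-channel configurations where brute-force DFT oracles
are compared bin by bin.

## Limitations

* **Harmonic locking at the heartbeat band edge.** MTI phase distortion
  places respiration harmonics inside the 1.0-1.8 Hz band. When the heart
  rate sits at the band edge (1.0 Hz, where the band-pass already halves
  the line) and a respiration harmonic lands nearby, the harmonic can win
  the dominant-frequency contest; across the recovery grid this loses the
  heart rate in ~4% of runs (concentrated at respiration 0.25/0.35 Hz with
  heart 1.0 Hz), mirroring the occasional gross errors real mean-cancelled
  radar HR estimation exhibits. Respiration recovery is unaffected.
* The phase-fidelity identity (fused phase = `4*pi*R(t)/lambda` + const to
  < 1e-6 rad) holds for the fusion front end on noiseless scenes; after
  MTI it cannot hold in exact arithmetic, by the argument above.
* The MAT reader covers the level-5 dialect (real/complex numeric
  matrices, compressed or not); HDF5-based v7.3 files are rejected with an
  informative error.
* EMD has no unique definition; the sifting parameters here (envelope
  boundary handling, stopping criterion) are documented defaults, and IMFs
  beyond the first two of a two-tone signal depend on them.
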