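# emowave

Simulation and analysis pipeline for a 60 GHz FMCW-radar multimodal emotion
dataset: non-contact vital-sign extraction from raw radar ADC data,
PPG/GSR conditioning, signal-quality validation, windowed feature
extraction, self-assessment (SAM) rating statistics, and a
subject-dependent RBF-SVM emotion-classification baseline on valence,
arousal and dominance.

## Who this is for

Researchers working with contact-free physiological sensing or affective
computing who want a tested, end-to-end reference implementation of the
processing chain such datasets define — runnable entirely on synthetic
data, so every stage can be exercised and validated without downloading
the multi-gigabyte recordings.

## The core computation

An FMCW radar chirp of slope *S* mixes with its echo to an IF tone with

- frequency *f*<sub>IF</sub> = *S*·2*R*/*c* (range), and
- phase φ = 4π*R*/λ (sub-wavelength displacement; λ = 5 mm at 60 GHz),

so chest-wall motion — respiration at mm scale, heartbeat at sub-mm scale —
phase-modulates the echo. The extraction chain per trial is

1. fast-time FFT per chirp → range–time matrix (bin size Δr = 0.0451 m);
2. MTI static-clutter suppression by per-bin slow-time mean cancellation;
3. selection of the K = 5 strongest bins and amplitude-weighted fusion of
   their unwrapped slow-time phases;
4. averaging over the 12 virtual channels, first-order differencing
   (the *vital sign*), and zero-phase Butterworth band-passes:
   0.1–0.5 Hz (respiration, 4th order) and 1.0–1.8 Hz (heartbeat, 6th
   order).

Downstream, each signal contributes per-window features (HRV from beat
intervals, Hilbert–Huang IMF statistics, Higuchi fractal dimension,
non-stationarity index, PSD band energies — 32 mmWave / 28 PPG / 24 GSR
over twelve 5 s windows of each trial's final 60 s), ratings are binarized
at the scale midpoint 5, and a per-participant RBF-SVM (75/25 chronological
split, train-statistics Z-scoring, 11×6 grid search) provides the
classification baseline. The methods vignette
(`vignettes/radar-emotion-pipeline.Rmd`) documents every model, parameter
and numerical choice.

## Worked example

Simulate one trial with known physiology and recover it:

```r
library(emowave)

cfg <- radar_config()                       # the study's 60 GHz device
scene <- scene_model(
  target = chest_motion(resp_rate = 0.25,   # 15 breaths/min, 3 mm
                        heart_rate = 1.2),  # 72 bpm, 0.1 mm
  seed = 21)
cube <- simulate_adc_cube(cfg, scene, duration = 60)
vs <- extract_vital_sign(cube, cfg)

dominant_frequency(vs$respiration, 100, c(0.05, 0.55))  # 0.2502 Hz
dominant_frequency(vs$heartbeat,   100, c(0.8, 2.0))    # 1.1993 Hz
```

The respiration estimate lands within 0.0002 Hz of the simulated
15 breaths/min and the heart estimate within 0.04 bpm of 72 bpm. The same
workflow at cohort scale lives in `analysis/01…07`; for example
`analysis/04_signal_quality.R` prints, for the shipped 6-trial synthetic
cohort,

```
heart-rate agreement (radar vs PPG): MAE 0.24 bpm, median 0.27 bpm,
mean relative error 0.29%
```

and `analysis/06_ratings_analysis.R` reports the synthetic 15-participant
rating consistency (mean per-clip CV 0.23 / 0.31 / 0.29 for
valence/arousal/dominance) and the threshold-5 class distribution.

## Layout

```
R/                  implementation (simulators, radar chain, physio chains,
                    features, ratings, classifier, dataset I/O incl. a
                    minimal MAT level-5 reader/writer)
analysis/01…07      numbered workflow drivers over a synthetic cohort
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/          methods vignette
inst/extdata/       published per-clip rating summary and sample counts
```
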