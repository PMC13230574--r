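Package: emowave
Title: FMCW Radar Vital-Sign Extraction and Multimodal Emotion-Recognition Baseline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a millimeter-wave radar
    emotion dataset: synthetic FMCW raw ADC generation with chest-wall motion,
    range-FFT / moving-target-indication / multi-bin phase-fusion vital-sign
    extraction, PPG and GSR conditioning, band-split SNR and heart-rate
    agreement validation, windowed feature extraction (HRV, Hilbert-Huang,
    Higuchi fractal dimension, spectral bands), self-assessment rating
    statistics, and a subject-dependent RBF-SVM classification baseline on
    valence, arousal and dominance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
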