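test_that("window slices tile the final analysis tail exactly", {
  sl <- window_slices(6000, 100)
  expect_identical(nrow(sl), 12L)
  expect_true(all(sl[, "end"] - sl[, "start"] == 500L))
  # contiguous, covering exactly the last 60 s
  expect_identical(unname(sl[1, "start"]), 1L)
  expect_identical(unname(sl[12, "end"]), 6001L)
  covered <- unlist(lapply(seq_len(nrow(sl)),
                           function(i) sl[i, 1]:(sl[i, 2] - 1L)))
  expect_identical(unname(covered), 1:6000)

  # a 183 s record starts its tail at sample (183-60)*fs
  sl2 <- window_slices(18300, 100)
  expect_identical(unname(sl2[1, "start"]), 12301L)

  expect_error(window_slices(3000, 100), "shorter than the analysis tail")
})

test_that("beat detection finds periodic peaks and tolerates jitter", {
  fs <- 100
  t <- (0:5999) / fs
  beats <- detect_beats(sin(2 * pi * 1.2 * t), fs)
  expect_true(length(beats$beat_times) %in% c(71, 72))
  expect_true(all(abs(beats$nn_intervals - 1 / 1.2) <= 1 / fs + 1e-12))

  # jittered PPG: detected peak times within 20 ms of the generator's truth
  ppg <- simulate_ppg(heart_rate = 1.1, rate_jitter = 0.05, noise_sd = 0.03,
                      duration = 60, seed = 6)
  truth <- attr(ppg, "beat_times")
  det <- detect_beats(process_ppg(ppg)$samples, ppg$fs)
  hits <- vapply(truth, function(b) min(abs(det$beat_times - b)) <= 0.02,
                 logical(1))
  expect_gte(mean(hits), 0.95)

  # flat signal: no beats
  flat <- detect_beats(rep(0, 1000), fs)
  expect_length(flat$beat_times, 0)
  expect_length(flat$nn_intervals, 0)
})

test_that("HRV features follow their definitions on constructed series", {
  # metronomic beats
  const <- structure(list(beat_times = seq(0, 60, by = 1 / 1.2),
                          nn_intervals = rep(1 / 1.2, 72)),
                     class = "beat_series")
  h <- hrv_features(const)
  expect_equal(unname(h["meanNN"]), 1 / 1.2, tolerance = 1e-12)
  expect_equal(unname(h["medianNN"]), 1 / 1.2, tolerance = 1e-12)
  expect_equal(unname(h[c("SDNN", "RMSSD", "SD1", "pNN50", "sdRate")]),
               rep(0, 5))
  expect_equal(unname(h["meanRate"]), 72, tolerance = 1e-9)

  # alternating 0.80/0.86 s: every successive difference is 60 ms
  alt <- structure(list(beat_times = cumsum(c(0, rep(c(0.80, 0.86), 20))),
                        nn_intervals = rep(c(0.80, 0.86), 20)),
                   class = "beat_series")
  expect_equal(unname(hrv_features(alt)["pNN50"]), 100)

  # SD1 is RMSSD/sqrt(2): Poincare identity over a random battery
  set.seed(3)
  for (i in 1:10) {
    nn <- runif(sample(3:40, 1), 0.6, 1.1)
    b <- structure(list(beat_times = cumsum(c(0, nn)), nn_intervals = nn),
                   class = "beat_series")
    hv <- hrv_features(b)
    expect_equal(unname(hv["SD1"]), unname(hv["RMSSD"]) / sqrt(2),
                 tolerance = 1e-14)
    expect_equal(unname(hv["meanRate"]), mean(60 / nn), tolerance = 1e-12)
  }

  # fewer than 3 intervals: flagged missing
  short <- structure(list(beat_times = c(0, 0.8), nn_intervals = 0.8),
                     class = "beat_series")
  expect_true(attr(hrv_features(short), "missing"))
})

test_that("NSI separates stationary noise from drifting signals", {
  set.seed(12)
  n <- 2000
  noise_nsi <- replicate(20, nsi(rnorm(n)))
  # segment means of N(0,1)/sd over n/10 samples have SD ~ 1/sqrt(n/10)
  expect_lt(mean(noise_nsi), 3 / sqrt(n / 10))
  ramp_nsi <- nsi(seq(0, 1, length.out = n))
  expect_gt(ramp_nsi, 10 * mean(noise_nsi))
  expect_identical(nsi(rep(2, 100)), 0)
})

test_that("Higuchi fractal dimension hits the known anchors", {
  expect_equal(hfd(seq(0, 1, length.out = 500)), 1, tolerance = 0.02)
  set.seed(5)
  wn <- replicate(5, hfd(rnorm(5000)))
  expect_true(all(wn > 1.85 & wn <= 2.05))
  s <- hfd(sin(2 * pi * 3 * (0:999) / 100))
  expect_gt(s, 1)
  expect_lt(s, 1.3)
})

test_that("PSD band energy localizes tones and spreads white noise evenly", {
  fs <- 100
  t <- (0:5999) / fs   # a 60 s analysis tail: enough cycles to limit leakage
  tone <- sin(2 * pi * 0.25 * t)
  bands <- list(c(0, 0.1), c(0.1, 0.2), c(0.2, 0.3), c(0.3, 0.4))
  e <- vapply(bands, function(b) psd_band_energy(tone, fs, b), numeric(1))
  expect_identical(which.max(e), 3L)
  expect_true(all(e[-3] < 0.05 * e[3]))

  expect_true(all(vapply(bands, function(b)
    psd_band_energy(rep(0, 500), fs, b), numeric(1)) == 0))

  # long white-noise record: equal-width bands carry comparable energy
  set.seed(7)
  w <- rnorm(5e4)
  ew <- vapply(list(c(5, 10), c(10, 15), c(15, 20)), function(b)
    psd_band_energy(w, fs, b), numeric(1))
  expect_lt(max(ew) / min(ew), 1.3)
})

test_that("Hilbert-Huang features resolve mono- and two-tone signals", {
  fs <- 100
  t <- (0:2999) / fs
  mono <- 0.8 * sin(2 * pi * 1.2 * t)
  hm <- hht_features(mono, fs)
  expect_equal(unname(hm["imf1_freq"]), 1.2, tolerance = 0.05 * 1.2)
  expect_equal(unname(hm["imf1_amp"]), 0.8, tolerance = 0.05 * 0.8)

  two <- sin(2 * pi * 1.5 * t) + sin(2 * pi * 0.25 * t)
  ht <- hht_features(two, fs)
  expect_equal(unname(ht["imf1_freq"]), 1.5, tolerance = 0.15)
  expect_equal(unname(ht["imf2_freq"]), 0.25, tolerance = 0.025)

  hc <- hht_features(rep(1, 500), fs)
  expect_true(all(hc == 0))
  expect_identical(attr(hc, "missing_imfs"), 4)
})

test_that("feature vectors have stable schemas of 32/28/24 values", {
  expect_length(feature_schema("mmwave"), 32)
  expect_length(feature_schema("ppg"), 28)
  expect_length(feature_schema("gsr"), 24)

  fs <- 100
  t <- (0:499) / fs
  beats <- detect_beats(sin(2 * pi * 1.2 * (0:999) / fs), fs)
  v <- mmwave_feature_vector(sin(2 * pi * 0.3 * t), sin(2 * pi * 0.25 * t),
                             sin(2 * pi * 1.2 * t), fs, beats)
  expect_identical(names(v), feature_schema("mmwave"))
  expect_length(v, 32)

  p <- ppg_feature_vector(sin(2 * pi * 1.2 * t), fs, beats)
  expect_identical(names(p), feature_schema("ppg"))
  expect_length(p, 28)

  g <- gsr_feature_vector(2 + 0.1 * t, fs)
  expect_identical(names(g), feature_schema("gsr"))
  expect_length(g, 24)
})

test_that("degenerate inputs produce the documented feature values", {
  fs <- 100
  t <- (0:499) / fs
  beats <- detect_beats(sin(2 * pi * 1.2 * (0:999) / fs), fs)
  const <- mmwave_feature_vector(rep(2.5, 500), sin(2 * pi * 0.25 * t),
                                 sin(2 * pi * 1.2 * t), fs, beats)
  expect_equal(unname(const[c("vs_mean", "vs_sd", "vs_mad1", "vs_mad2",
                              "vs_norm_mad1", "vs_norm_mad2", "vs_nsi")]),
               c(2.5, 0, 0, 0, 0, 0, 0))

  # GSR ramp: first derivative constant, second derivative zero
  g <- gsr_feature_vector(2 + 0.01 * (0:499), fs)
  expect_equal(unname(g["d1_sd"]), 0, tolerance = 1e-12)
  expect_equal(unname(g["d1_mean"]), 0.01, tolerance = 1e-12)
  expect_true(all(abs(g[c("d2_median", "d2_mean", "d2_sd", "d2_min",
                          "d2_max")]) < 1e-12))

  # constant GSR: stats collapse, normalized range 0
  gc <- gsr_feature_vector(rep(3, 500), fs)
  expect_equal(unname(gc[c("sig_median", "sig_mean", "sig_min", "sig_max")]),
               rep(3, 4))
  expect_equal(unname(gc[c("sig_sd", "sig_norm_range")]), c(0, 0))
})

test_that("trial feature matrices have 12 windows and honor the schema", {
  # synthetic PPG trial, 70 s so the tail is a proper suffix
  ppg <- process_ppg(simulate_ppg(heart_rate = 1.2, duration = 70, seed = 2))
  fm <- ppg_trial_features(ppg)
  expect_identical(dim(fm), c(12L, 28L))
  expect_identical(colnames(fm), feature_schema("ppg"))
  expect_true(all(is.finite(fm)))
  # a clean 72 bpm pulse yields a ~72 bpm meanRate everywhere
  expect_true(all(abs(fm[, "meanRate"] - 72) < 2))

  gsr <- process_gsr(simulate_gsr(duration = 70, seed = 2))
  gm <- gsr_trial_features(gsr)
  expect_identical(dim(gm), c(12L, 24L))

  # features ignore everything before the analysis tail
  ppg_long <- process_ppg(simulate_ppg(heart_rate = 1.2, duration = 70,
                                       seed = 2))
  head_pad <- physio_signal(c(rnorm(1000), ppg_long$samples), 200, "a.u.")
  fm_pad <- ppg_trial_features(head_pad)
  expect_equal(fm_pad, fm, tolerance = 1e-12)
})
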