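#' Analysis windowing specification
#'
#' Features are computed over the final `tail_seconds` of a trial with
#' non-overlapping windows: the defaults (60 s tail, 5 s windows, 5 s step)
#' yield 12 windows per trial.
#'
#' @param tail_seconds Analysis tail length in seconds.
#' @param window_seconds Window length in seconds.
#' @param step_seconds Step between window starts (default = window length).
#' @return A `window_spec` object.
#' @export
window_spec <- function(tail_seconds = 60, window_seconds = 5,
                        step_seconds = window_seconds) {
  stopifnot(tail_seconds > 0, window_seconds > 0,
            step_seconds == window_seconds,
            tail_seconds %% window_seconds == 0)
  structure(list(tail_seconds = tail_seconds,
                 window_seconds = window_seconds,
                 step_seconds = step_seconds),
            class = "window_spec")
}

#' Window slices over the analysis tail
#'
#' Non-overlapping, contiguous half-open `[start, end)` sample slices
#' (1-based starts) covering exactly the final `tail_seconds` of a record.
#'
#' @param n_samples Record length in samples.
#' @param fs Sampling rate in Hz.
#' @param spec A [window_spec()].
#' @return Integer matrix with columns `start`, `end`; one row per window.
#' @export
window_slices <- function(n_samples, fs, spec = window_spec()) {
  tail_n <- as.integer(round(spec$tail_seconds * fs))
  if (n_samples < tail_n) stop("record shorter than the analysis tail")
  win_n <- as.integer(round(spec$window_seconds * fs))
  n_win <- tail_n %/% win_n
  start0 <- as.integer(n_samples) - tail_n
  starts <- start0 + (seq_len(n_win) - 1L) * win_n + 1L
  cbind(start = starts, end = starts + win_n)
}

#' Detect heartbeats by prominence-thresholded peak picking
#'
#' Local maxima above an adaptive height threshold
#' (`median + 0.3 * (max - median)`), enforced to be at least 0.45 s apart
#' (refractory period) by greedy selection in descending height order.
#' This stands in for template-matching beat segmentation behind a stable
#' interface, so a different detector can be substituted.
#'
#' @param x Numeric series (heartbeat waveform or processed PPG), >= 5 s.
#' @param fs Sampling rate in Hz.
#' @param refractory Minimum beat separation in seconds (default 0.45).
#' @return A `beat_series`: list with `beat_times` (s, increasing) and
#'   `nn_intervals` (s); both empty when fewer than 2 beats are found.
#' @export
detect_beats <- function(x, fs, refractory = 0.45) {
  stopifnot(length(x) >= 5 * fs)
  cand <- local_maxima(x)
  thr <- stats::median(x) + 0.3 * (max(x) - stats::median(x))
  cand <- cand[x[cand] > thr]
  accepted <- integer(0)
  for (i in cand[order(-x[cand])]) {
    if (!length(accepted) || all(abs(i - accepted) >= refractory * fs))
      accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  if (length(accepted) < 2)
    return(structure(list(beat_times = numeric(0), nn_intervals = numeric(0)),
                     class = "beat_series"))
  times <- (accepted - 1) / fs
  structure(list(beat_times = times, nn_intervals = diff(times)),
            class = "beat_series")
}

#' Heart-rate-variability features
#'
#' Nine standard HRV statistics from normal-to-normal (NN) intervals:
#' meanNN, medianNN, SDNN, RMSSD (s); pNN50 (% of successive-interval
#' differences above 50 ms); meanRate, sdRate (bpm, from 60/NN); HRVTi
#' (interval count divided by the modal histogram bin count, bin width
#' 1/128 s); SD1 (s), the Poincare-plot dispersion perpendicular to the
#' identity line, computed from the perpendicular distances
#' `(NN[i+1] - NN[i]) / sqrt(2)`.
#'
#' @param beats A `beat_series` from [detect_beats()].
#' @return Named numeric vector of 9 values, or all-`NA` (flagged via
#'   attribute `missing = TRUE`) when fewer than 3 NN intervals exist.
#' @export
hrv_features <- function(beats) {
  nn <- beats$nn_intervals
  nms <- c("meanNN", "medianNN", "SDNN", "RMSSD", "pNN50",
           "meanRate", "sdRate", "HRVTi", "SD1")
  if (length(nn) < 3) {
    out <- stats::setNames(rep(NA_real_, 9), nms)
    attr(out, "missing") <- TRUE
    return(out)
  }
  d <- diff(nn)
  rmssd <- sqrt(mean(d^2))
  rate <- 60 / nn
  bins <- floor(nn / (1 / 128))
  hrvti <- length(nn) / max(table(bins))
  out <- c(meanNN = mean(nn), medianNN = stats::median(nn),
           SDNN = stats::sd(nn), RMSSD = rmssd,
           pNN50 = 100 * mean(abs(d) > 0.05),
           meanRate = mean(rate), sdRate = stats::sd(rate),
           HRVTi = hrvti,
           SD1 = sqrt(mean((d / sqrt(2))^2)))
  attr(out, "missing") <- FALSE
  out
}

#' Non-stationarity index
#'
#' The signal is variance-normalized, divided into `n_segments` contiguous
#' segments, and the sample SD of the segment means is returned. Constant
#' signals return 0.
#'
#' @param x Numeric series (length >= `n_segments`).
#' @param n_segments Number of segments (default 10).
#' @return Non-negative scalar.
#' @export
nsi <- function(x, n_segments = 10) {
  stopifnot(length(x) >= n_segments)
  s <- stats::sd(x)
  if (s == 0) return(0)
  z <- (x - mean(x)) / s
  seg <- cut(seq_along(z), breaks = n_segments, labels = FALSE)
  stats::sd(tapply(z, seg, mean))
}

#' Higuchi fractal dimension
#'
#' Higuchi's curve-length estimate: for each lag `k = 1..kmax` the mean
#' normalized curve length `L(k)` is computed over the `k` possible offsets,
#' and the slope of `log(L)` against `log(1/k)` is the fractal dimension
#' (1 for a straight line, approaching 2 for white noise).
#'
#' @param x Numeric series (length >= 10 * kmax).
#' @param kmax Maximum lag (default 10).
#' @return Estimated dimension.
#' @export
hfd <- function(x, kmax = 10) {
  n <- length(x)
  stopifnot(n >= 10 * kmax)
  lk <- vapply(seq_len(kmax), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      sum(abs(diff(x[idx]))) * (n - 1) / ((length(idx) - 1) * k) / k
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
  if (any(lk <= 0)) return(0)
  unname(stats::coef(stats::lm.fit(cbind(1, log(1 / seq_len(kmax))),
                                   log(lk)))[2])
}

# raw periodogram (rectangular window), zero-padded so the frequency grid
# is fine enough for 0.1 Hz-wide bands even on 5 s windows
periodogram <- function(x, fs, df_max = 0.025) {
  n <- length(x)
  nfft <- max(n, 2^ceiling(log2(fs / df_max)))
  p <- Mod(stats::fft(c(x, rep(0, nfft - n))))^2 / (n * fs)
  f <- (seq_len(nfft) - 1) * fs / nfft
  keep <- f < fs / 2
  list(freq = f[keep], psd = p[keep])
}

#' Average PSD energy in a frequency band
#'
#' Mean of the raw-periodogram PSD estimate over frequencies in `[lo, hi)`.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param band `c(lo, hi)` in Hz, inside (0, fs/2).
#' @return Mean PSD in the band.
#' @export
psd_band_energy <- function(x, fs, band) {
  stopifnot(length(band) == 2, band[1] < band[2], band[2] <= fs / 2)
  pg <- periodogram(x, fs)
  in_band <- pg$freq >= band[1] & pg$freq < band[2]
  if (!any(in_band)) stop("empty band after discretization")
  mean(pg$psd[in_band])
}

# shared statistical block: mean, SD, mean |d1|, mean |d2| of x and of its
# variance-normalized copy
stat_block <- function(x) {
  s <- stats::sd(x)
  z <- if (s > 0) (x - mean(x)) / s else rep(0, length(x))
  c(mean = mean(x), sd = s,
    mad1 = mean(abs(diff(x))), mad2 = mean(abs(diff(x, differences = 2))),
    norm_mad1 = mean(abs(diff(z))),
    norm_mad2 = mean(abs(diff(z, differences = 2))))
}

resp_bands <- list(c(0, 0.1), c(0.1, 0.2), c(0.2, 0.3), c(0.3, 0.4))
heart_bands <- list(c(1.0, 1.3), c(1.3, 1.6), c(1.6, 1.8))

#' Feature schemas
#'
#' Fixed, ordered feature-name lists for the three modalities: 32 features
#' for mmWave, 28 for PPG, 24 for GSR.
#'
#' @param signal_kind One of `"mmwave"`, `"ppg"`, `"gsr"`.
#' @return Character vector of feature names.
#' @export
feature_schema <- function(signal_kind = c("mmwave", "ppg", "gsr")) {
  signal_kind <- match.arg(signal_kind)
  hht_names <- as.vector(rbind(paste0("imf", 1:4, "_freq"),
                               paste0("imf", 1:4, "_amp")))
  hrv_names <- c("meanNN", "medianNN", "SDNN", "RMSSD", "pNN50",
                 "meanRate", "sdRate", "HRVTi", "SD1")
  switch(signal_kind,
    mmwave = c("vs_mean", "vs_sd", "vs_mad1", "vs_mad2",
               "vs_norm_mad1", "vs_norm_mad2", "vs_nsi", "vs_hfd",
               "resp_psd_0.0_0.1", "resp_psd_0.1_0.2",
               "resp_psd_0.2_0.3", "resp_psd_0.3_0.4",
               "hb_psd_1.0_1.3", "hb_psd_1.3_1.6", "hb_psd_1.6_1.8",
               hht_names, hrv_names),
    ppg = c("sig_mean", "sig_sd", "sig_mad1", "sig_mad2",
            "sig_norm_mad1", "sig_norm_mad2", "sig_nsi", "sig_hfd",
            "psd_1.0_1.3", "psd_1.3_1.6", "psd_1.6_1.8",
            hht_names, hrv_names),
    gsr = {
      blocks <- c("sig", "d1", "d2")
      stats <- c("median", "mean", "sd", "min", "max", "norm_range")
      c(as.vector(t(outer(blocks, stats, paste, sep = "_"))),
        paste0("psd_", c("median", "mean", "sd", "max", "min", "range")))
    })
}

#' mmWave feature vector for one analysis window
#'
#' Ordered concatenation: mean and SD of the vital sign; mean absolute first
#' and second differences of the vital sign and of its variance-normalized
#' copy; NSI and HFD of the vital sign; mean respiration-PSD energy in four
#' 0.1 Hz bands (0-0.4 Hz); mean heartbeat-PSD energy in three bands
#' (1.0-1.8 Hz); eight Hilbert-Huang IMF features; nine HRV features --
#' 32 values.
#'
#' @param vital_sign,respiration,heartbeat Window-length series at `fs`.
#' @param fs Sampling rate in Hz.
#' @param beats A `beat_series` whose intervals cover this window (HRV is
#'   taken from here; pass trial-level beats to use the documented fallback).
#' @return Named numeric vector of 32 features.
#' @export
mmwave_feature_vector <- function(vital_sign, respiration, heartbeat, fs,
                                  beats) {
  v <- c(stat_block(vital_sign),
         nsi = nsi(vital_sign), hfd = hfd(vital_sign),
         vapply(resp_bands, function(b) psd_band_energy(respiration, fs, b),
                numeric(1)),
         vapply(heart_bands, function(b) psd_band_energy(heartbeat, fs, b),
                numeric(1)),
         hht_features(vital_sign, fs),
         hrv_features(beats))
  stats::setNames(as.numeric(v), feature_schema("mmwave"))
}

#' PPG feature vector for one analysis window
#'
#' Same construction as [mmwave_feature_vector()] minus the respiration PSD
#' block: statistics, NSI/HFD and PSD bands are computed on the processed
#' PPG itself -- 28 values.
#'
#' @param processed_ppg Window-length conditioned PPG series.
#' @param fs Sampling rate in Hz.
#' @param beats A `beat_series` for HRV.
#' @return Named numeric vector of 28 features.
#' @export
ppg_feature_vector <- function(processed_ppg, fs, beats) {
  v <- c(stat_block(processed_ppg),
         nsi = nsi(processed_ppg), hfd = hfd(processed_ppg),
         vapply(heart_bands, function(b) psd_band_energy(processed_ppg, fs, b),
                numeric(1)),
         hht_features(processed_ppg, fs),
         hrv_features(beats))
  stats::setNames(as.numeric(v), feature_schema("ppg"))
}

# median/mean/sd/min/max/normalized-range block; normalized range is
# (max - min) / mean with a zero-mean guard
range_stats <- function(x) {
  m <- mean(x)
  c(median = stats::median(x), mean = m, sd = stats::sd(x),
    min = min(x), max = max(x),
    norm_range = if (abs(m) < 1e-12) 0 else (max(x) - min(x)) / m)
}

#' GSR feature vector for one analysis window
#'
#' Median, mean, SD, minimum, maximum and normalized range of the
#' conductance signal, of its first derivative and of its second derivative
#' (18 values), plus median, mean, SD, maximum, minimum and range of the
#' periodogram PSD restricted to 0-2 Hz (6 values) -- 24 features.
#'
#' @param conductance Window-length conductance series (uS).
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of 24 features.
#' @export
gsr_feature_vector <- function(conductance, fs) {
  d1 <- diff(conductance)
  d2 <- diff(conductance, differences = 2)
  pg <- periodogram(conductance, fs)
  p <- pg$psd[pg$freq >= 0 & pg$freq <= 2]
  v <- c(range_stats(conductance), range_stats(d1), range_stats(d2),
         stats::median(p), mean(p), stats::sd(p), max(p), min(p),
         max(p) - min(p))
  stats::setNames(as.numeric(v), feature_schema("gsr"))
}

# HRV for one window from trial-level beats: intervals whose beats fall
# inside [t0, t1); when fewer than 3 remain, the trial-level HRV is carried
# forward (flagged).
window_hrv_beats <- function(beats, t0, t1) {
  keep <- beats$beat_times >= t0 & beats$beat_times < t1
  times <- beats$beat_times[keep]
  structure(list(beat_times = times, nn_intervals = diff(times)),
            class = "beat_series")
}

#' Windowed feature matrix for an mmWave trial
#'
#' Applies [window_slices()] to the final 60 s of the vital-sign bundle and
#' computes [mmwave_feature_vector()] per window. Beats are detected once on
#' the heartbeat waveform of the full analysis tail; windows with fewer than
#' 3 NN intervals carry the trial-level HRV forward (recorded in attribute
#' `hrv_fallback`).
#'
#' @param bundle A `vital_sign_bundle` from [extract_vital_sign()].
#' @param spec A [window_spec()].
#' @return Numeric matrix `windows x 32` with schema column names.
#' @export
mmwave_trial_features <- function(bundle, spec = window_spec()) {
  fs <- bundle$slow_time_rate
  sl <- window_slices(length(bundle$vital_sign), fs, spec)
  tail_idx <- sl[1, "start"]:(sl[nrow(sl), "end"] - 1L)
  trial_beats <- detect_beats(bundle$heartbeat[tail_idx], fs)
  trial_beats$beat_times <- trial_beats$beat_times + (sl[1, "start"] - 1) / fs
  windowed_features(sl, fs, trial_beats, feature_schema("mmwave"),
    function(i0, i1, b) {
      idx <- i0:(i1 - 1L)
      mmwave_feature_vector(bundle$vital_sign[idx], bundle$respiration[idx],
                            bundle$heartbeat[idx], fs, b)
    })
}

#' Windowed feature matrix for a PPG trial
#'
#' @param processed A conditioned [physio_signal()] from [process_ppg()].
#' @param spec A [window_spec()].
#' @return Numeric matrix `windows x 28` with schema column names.
#' @export
ppg_trial_features <- function(processed, spec = window_spec()) {
  fs <- processed$fs
  x <- processed$samples
  sl <- window_slices(length(x), fs, spec)
  tail_idx <- sl[1, "start"]:(sl[nrow(sl), "end"] - 1L)
  trial_beats <- detect_beats(x[tail_idx], fs)
  trial_beats$beat_times <- trial_beats$beat_times + (sl[1, "start"] - 1) / fs
  windowed_features(sl, fs, trial_beats, feature_schema("ppg"),
    function(i0, i1, b) ppg_feature_vector(x[i0:(i1 - 1L)], fs, b))
}

#' Windowed feature matrix for a GSR trial
#'
#' @param processed A conditioned [physio_signal()] from [process_gsr()].
#' @param spec A [window_spec()].
#' @return Numeric matrix `windows x 24` with schema column names.
#' @export
gsr_trial_features <- function(processed, spec = window_spec()) {
  fs <- processed$fs
  x <- processed$samples
  sl <- window_slices(length(x), fs, spec)
  out <- t(apply(sl, 1, function(s) gsr_feature_vector(x[s[1]:(s[2] - 1L)], fs)))
  colnames(out) <- feature_schema("gsr")
  out
}

# shared window loop with trial-level HRV fallback
windowed_features <- function(sl, fs, trial_beats, schema, fun) {
  trial_hrv_missing <- attr(hrv_features(trial_beats), "missing")
  out <- matrix(NA_real_, nrow(sl), length(schema),
                dimnames = list(NULL, schema))
  fallback <- logical(nrow(sl))
  for (i in seq_len(nrow(sl))) {
    t0 <- (sl[i, "start"] - 1) / fs
    t1 <- (sl[i, "end"] - 1) / fs
    wb <- window_hrv_beats(trial_beats, t0, t1)
    if (length(wb$nn_intervals) < 3 && !trial_hrv_missing) {
      wb <- trial_beats
      fallback[i] <- TRUE
    }
    out[i, ] <- fun(sl[i, "start"], sl[i, "end"], wb)
  }
  attr(out, "hrv_fallback") <- fallback
  out
}
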