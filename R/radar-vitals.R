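#' Range FFT of an ADC cube
#'
#' Per channel, applies the discrete Fourier transform along fast time
#' (rectangular window, no zero padding) for each chirp and stacks the
#' spectra along slow time, yielding one range-time matrix (RTM) per channel.
#' Bin `b` (0-based) maps to range `b * delta_r`.
#'
#' @param cube An `adc_cube` from [simulate_adc_cube()] or [read_adc_mat()].
#' @param config A [radar_config()] consistent with the cube dimensions.
#' @return A list of `range_time_matrix` objects (complex
#'   `adc_samples x n_chirps` matrices with attributes `range_bin_size` and
#'   `slow_time_rate`), one per virtual channel.
#' @export
range_fft <- function(cube, config) {
  stopifnot(inherits(config, "radar_config"))
  d <- dim(cube)
  if (length(d) != 3 || d[1] != config$n_virtual || d[2] != config$adc_samples)
    stop("cube dimensions inconsistent with config")
  dr <- range_resolution(config)
  lapply(seq_len(d[1]), function(ch) {
    rtm <- stats::mvfft(matrix(cube[ch, , ], d[2], d[3]))
    structure(rtm, range_bin_size = dr, slow_time_rate = config$frame_rate,
              class = c("range_time_matrix", "matrix"))
  })
}

#' Moving-target indication by mean cancellation
#'
#' Suppresses static clutter by subtracting, within each range bin, the
#' complex slow-time mean from every sample of that bin. Stationary
#' reflections are constant along slow time and cancel; moving targets keep
#' their slow-time variance (the variance is mean-invariant).
#'
#' @param rtm A `range_time_matrix`.
#' @return The mean-cancelled `range_time_matrix`.
#' @export
mti_mean_cancellation <- function(rtm) {
  if (ncol(rtm) < 2) stop("MTI requires at least 2 chirps")
  out <- rtm - rowMeans(rtm)
  attributes(out) <- attributes(rtm)
  out
}

#' Select the strongest range bins for phase fusion
#'
#' Finds the `k` bins inside a range search window with the largest mean
#' slow-time magnitude, and assigns each a weight proportional to its mean
#' amplitude (weights sum to 1). Ties are broken toward the lower bin index.
#'
#' @param rtm A `range_time_matrix`.
#' @param k Number of bins to fuse (default 5).
#' @param search_window `c(min_m, max_m)` range window restricting the
#'   search; default 0.3-1.5 m, covering the 0.6-0.9 m seating range with
#'   margin while excluding far clutter.
#' @return A `bin_selection`: list with 0-based `bin_indices` (descending
#'   mean amplitude), `mean_amplitudes`, and normalized `weights`.
#' @export
select_bins <- function(rtm, k = 5, search_window = c(0.3, 1.5)) {
  stopifnot(k >= 1, length(search_window) == 2,
            search_window[1] < search_window[2])
  dr <- attr(rtm, "range_bin_size")
  bins0 <- seq_len(nrow(rtm)) - 1
  in_win <- bins0 * dr >= search_window[1] & bins0 * dr <= search_window[2]
  if (!any(in_win)) stop("search window outside the RTM's range span")
  if (sum(in_win) < k) stop("search window contains fewer than k bins")
  amp <- rowMeans(Mod(rtm))
  cand <- bins0[in_win]
  # stable order: descending amplitude, ties toward lower bin index
  ord <- cand[order(-amp[in_win], cand)]
  sel <- as.integer(ord[seq_len(k)])
  a <- amp[sel + 1]
  structure(list(bin_indices = sel, mean_amplitudes = a,
                 weights = a / sum(a)),
            class = "bin_selection")
}

#' Unwrap a phase series
#'
#' Restores phase continuity by applying a -2*pi shift whenever the
#' successive change exceeds +pi and a +2*pi shift when it is below -pi; the
#' first sample is kept as-is, and successive differences of the output lie
#' in (-pi, pi].
#'
#' @param wrapped Phase series in radians.
#' @return Unwrapped series, same length.
#' @export
unwrap_phase <- function(wrapped) {
  if (length(wrapped) < 2) return(wrapped)
  d <- diff(wrapped)
  shift <- -2 * pi * (d > pi) + 2 * pi * (d < -pi)
  # repeat until every step is inside (-pi, pi] (multi-wrap steps)
  adj <- d + shift
  while (any(adj > pi | adj < -pi)) {
    adj <- adj - 2 * pi * (adj > pi) + 2 * pi * (adj < -pi)
  }
  wrapped[1] + c(0, cumsum(adj))
}

#' Fuse unwrapped phases from the selected range bins
#'
#' For each selected bin, extracts the complex argument of the slow-time
#' series, unwraps it, and forms the amplitude-weighted sum. Bins containing
#' zero-magnitude samples (undefined phase) are dropped with a warning and
#' the remaining weights renormalized.
#'
#' @param rtm A `range_time_matrix`.
#' @param selection A [select_bins()] result valid for `rtm`.
#' @return Fused unwrapped phase series (radians), length `ncol(rtm)`.
#' @export
fuse_phase <- function(rtm, selection) {
  stopifnot(inherits(selection, "bin_selection"),
            all(selection$bin_indices + 1 <= nrow(rtm)))
  keep <- vapply(selection$bin_indices, function(b) {
    all(Mod(rtm[b + 1, ]) > 0)
  }, logical(1))
  if (!any(keep)) stop("all selected bins have zero-magnitude samples")
  if (!all(keep)) {
    warning(sprintf("%d bin(s) with undefined phase dropped from fusion",
                    sum(!keep)))
  }
  idx <- selection$bin_indices[keep]
  w <- selection$weights[keep]
  w <- w / sum(w)
  phases <- vapply(idx, function(b) unwrap_phase(Arg(rtm[b + 1, ])),
                   numeric(ncol(rtm)))
  as.numeric(phases %*% w)
}

#' Extract vital signs from a raw ADC cube
#'
#' Full extraction chain: per-channel range FFT, static-clutter suppression
#' by mean cancellation, selection of the K strongest bins, phase unwrapping
#' and amplitude-weighted fusion, arithmetic averaging of the fused phase
#' across the virtual channels, first-order differencing (removing
#' low-frequency drift), and band-pass filtering: a 4th-order Butterworth at
#' 0.1-0.5 Hz for respiration and a 6th-order Butterworth at 1.0-1.8 Hz for
#' heartbeat, both applied forward-backward (zero phase).
#'
#' @param cube An `adc_cube`.
#' @param config A [radar_config()].
#' @param k Number of fused bins per channel (default 5).
#' @param search_window Range window for bin selection, meters.
#' @return A `vital_sign_bundle`: list with `fused_phase` (length N_chirp),
#'   `vital_sign` (first difference, length N_chirp - 1), `respiration`,
#'   `heartbeat` (same length as `vital_sign`) and `slow_time_rate`.
#' @export
extract_vital_sign <- function(cube, config, k = 5,
                               search_window = c(0.3, 1.5)) {
  d <- dim(cube)
  if (d[3] < 10 * config$frame_rate)
    stop("record shorter than 10 s of slow time")
  fs <- config$frame_rate
  acc <- numeric(d[3])
  rtms <- range_fft(cube, config)
  for (rtm in rtms) {
    rtm <- mti_mean_cancellation(rtm)
    sel <- select_bins(rtm, k = k, search_window = search_window)
    acc <- acc + fuse_phase(rtm, sel)
  }
  fused <- acc / d[1]
  vital <- diff(fused)
  resp <- butter_filtfilt(vital, 4, c(0.1, 0.5), "pass", fs)
  heart <- butter_filtfilt(vital, 6, c(1.0, 1.8), "pass", fs)
  structure(list(fused_phase = fused, vital_sign = vital,
                 respiration = resp, heartbeat = heart,
                 slow_time_rate = fs),
            class = "vital_sign_bundle")
}
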