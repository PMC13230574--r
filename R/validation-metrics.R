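#' Band-split signal-to-noise ratio
#'
#' Splits the record at a cutoff frequency with a matched pair of zero-phase
#' Butterworth low-pass / high-pass filters (default 3rd order) and returns
#' `10 * log10(M_signal / M_noise)` where the two M are the mean square
#' amplitudes of the low-pass (signal) and high-pass (noise) components.
#' Conventional cutoffs: 15 Hz for PPG, 1 Hz for GSR.
#'
#' @param signal A [physio_signal()].
#' @param cutoff Boundary frequency in Hz (< fs/2).
#' @param order Filter order (default 3).
#' @return SNR in dB; `Inf` if the noise band carries zero power.
#' @export
snr_db <- function(signal, cutoff, order = 3) {
  stopifnot(inherits(signal, "physio_signal"), cutoff < signal$fs / 2)
  lo <- butter_filtfilt(signal$samples, order, cutoff, "low", signal$fs)
  hi <- butter_filtfilt(signal$samples, order, cutoff, "high", signal$fs)
  m_noise <- mean(hi^2)
  if (m_noise == 0) return(Inf)
  10 * log10(mean(lo^2) / m_noise)
}

#' Dominant frequency within a band
#'
#' Frequency of the magnitude-spectrum maximum inside `band`, computed on a
#' zero-padded FFT whose grid spacing is at most 0.005 Hz.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param band `c(lo, hi)` in Hz, within (0, fs/2).
#' @return Dominant frequency in Hz.
#' @export
dominant_frequency <- function(x, fs, band) {
  stopifnot(length(band) == 2, band[1] < band[2], band[1] > 0,
            band[2] < fs / 2)
  n <- length(x)
  nfft <- max(n, 2^ceiling(log2(fs / 0.005)))
  spec <- Mod(stats::fft(c(x - mean(x), rep(0, nfft - n))))
  f <- (seq_len(nfft) - 1) * fs / nfft
  in_band <- f >= band[1] & f <= band[2]
  if (!any(in_band)) stop("empty band")
  f[in_band][which.max(spec[in_band])]
}

#' Heart-rate agreement between radar and reference
#'
#' Element-wise absolute differences between radar-derived and reference
#' per-trial heart rates, summarized as MAE, median absolute error, SD of
#' the absolute errors, and mean relative error (`mean(|diff| / ref)`).
#'
#' @param mm_hr Radar heart rates in bpm, one per trial.
#' @param ref_hr Reference (e.g. PPG) heart rates in bpm, equal length.
#' @return An `hr_agreement` list: `abs_errors`, `mae`, `median_ae`, `sd_ae`,
#'   `mean_relative_error`.
#' @export
hr_agreement <- function(mm_hr, ref_hr) {
  if (length(mm_hr) != length(ref_hr) || length(mm_hr) < 1)
    stop("rate lists must have equal length >= 1")
  if (any(ref_hr <= 0)) stop("non-positive reference rate")
  ae <- abs(mm_hr - ref_hr)
  structure(list(abs_errors = ae,
                 mae = mean(ae),
                 median_ae = stats::median(ae),
                 sd_ae = if (length(ae) > 1) stats::sd(ae) else 0,
                 mean_relative_error = mean(ae / ref_hr)),
            class = "hr_agreement")
}
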