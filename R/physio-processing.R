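#' Condition a raw PPG signal
#'
#' Chain: 4th-order Butterworth band-pass 0.6-5 Hz (zero phase), linear
#' detrend (subtracting the least-squares straight-line fit), then a centered
#' moving average of 20 samples (0.1 s at the native 200 Hz; the window is
#' rescaled to 0.1 s for other rates). Output is approximately zero-mean.
#'
#' @param raw A [physio_signal()] in `"a.u."`.
#' @return A conditioned [physio_signal()] of equal length.
#' @export
process_ppg <- function(raw) {
  stopifnot(inherits(raw, "physio_signal"), raw$unit == "a.u.")
  n <- length(raw$samples)
  if (n < 3 * raw$fs) stop("record shorter than 3x the filter transient")
  x <- butter_filtfilt(raw$samples, 4, c(0.6, 5), "pass", raw$fs)
  t <- seq_len(n)
  x <- stats::residuals(stats::lm.fit(cbind(1, t), x))
  win <- max(1L, as.integer(round(0.1 * raw$fs)))
  physio_signal(moving_average(x, win), raw$fs, "a.u.")
}

# Centered moving average with edge truncation: near the boundaries the
# window shrinks to the available samples, avoiding phase lag and padding.
moving_average <- function(x, win) {
  if (win <= 1) return(x)
  half_l <- (win - 1L) %/% 2L
  half_r <- win - 1L - half_l
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Convert GSR resistance to conductance
#'
#' `uS = 1000 / kOhm`, so the 100 kOhm end of the sensor range maps to 10 uS.
#' The conversion is an exact involution with [conductance_to_resistance()].
#'
#' @param kohm Resistance values in kOhm.
#' @return Conductance in uS.
#' @export
resistance_to_conductance <- function(kohm) {
  if (any(kohm <= 0)) stop("non-positive resistance")
  1000 / kohm
}

#' @rdname resistance_to_conductance
#' @param us Conductance values in uS.
#' @export
conductance_to_resistance <- function(us) {
  if (any(us <= 0)) stop("non-positive conductance")
  1000 / us
}

#' Condition a raw GSR signal
#'
#' Converts the sensor's resistance trace (kOhm) to skin conductance (uS),
#' then applies a zero-phase 3rd-order Butterworth low-pass at 1 Hz.
#'
#' @param raw A [physio_signal()] in `"kOhm"`.
#' @return A conditioned [physio_signal()] in `"uS"`, equal length.
#' @export
process_gsr <- function(raw) {
  stopifnot(inherits(raw, "physio_signal"), raw$unit == "kOhm")
  g <- resistance_to_conductance(raw$samples)
  physio_signal(butter_filtfilt(g, 3, 1, "low", raw$fs), raw$fs, "uS")
}
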