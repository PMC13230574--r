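#' Uniformly sampled physiological signal
#'
#' Light container tying a numeric series to its sampling rate and unit.
#' Units in use: `"a.u."` for PPG, `"kOhm"` for raw GSR resistance, `"uS"`
#' for GSR conductance.
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param unit Unit tag.
#' @return A `physio_signal` object.
#' @export
physio_signal <- function(samples, fs, unit = "a.u.") {
  stopifnot(is.numeric(samples), length(samples) >= 1, fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs, unit = unit),
            class = "physio_signal")
}

#' @export
print.physio_signal <- function(x, ...) {
  cat(sprintf("<physio_signal> %d samples @ %g Hz [%s], %.1f s\n",
              length(x$samples), x$fs, x$unit, length(x$samples) / x$fs))
  invisible(x)
}
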