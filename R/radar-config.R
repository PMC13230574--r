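# Speed of light used throughout, m/s. The radar-engineering convention
# (3e8 exactly) is adopted so that derived quantities agree with the
# device datasheet values to their printed precision.
SPEED_OF_LIGHT <- 3e8

#' FMCW radar configuration
#'
#' Bundles the chirp and frame parameters of an FMCW radar together with
#' derived quantities (wavelength, number of virtual channels). Defaults are
#' the 60 GHz TDM-MIMO configuration used for data collection: 3 Tx x 4 Rx
#' virtual array, 100 Hz frame rate, 256 ADC samples per chirp at 5.12 MHz.
#'
#' @param start_frequency Chirp start frequency f_c in Hz.
#' @param bandwidth Full chirp sweep bandwidth B in Hz.
#' @param slope Frequency-modulation slope S in Hz/s.
#' @param adc_sample_rate Fast-time sampling rate in Hz.
#' @param adc_samples Fast-time samples per chirp.
#' @param n_tx,n_rx Number of transmit / receive antennas; the virtual array
#'   has `n_tx * n_rx` channels.
#' @param frame_rate Frames (here: chirps) per second; the slow-time rate in Hz.
#' @param chirp_loops Chirps per frame.
#' @param idle_time,adc_start_time,ramp_end_time Chirp timing in seconds.
#'
#' @return An object of class `radar_config`: a list with the inputs plus
#'   `n_virtual` (virtual channel count) and `wavelength` (c / f_c, m).
#' @examples
#' cfg <- radar_config()
#' range_resolution(cfg)
#' @export
radar_config <- function(start_frequency = 60e9,
                         bandwidth = 3790.97e6,
                         slope = 66.590e12,
                         adc_sample_rate = 5.12e6,
                         adc_samples = 256L,
                         n_tx = 3L,
                         n_rx = 4L,
                         frame_rate = 100,
                         chirp_loops = 1L,
                         idle_time = 7e-6,
                         adc_start_time = 5.92e-6,
                         ramp_end_time = 56.93e-6) {
  stopifnot(start_frequency > 0, bandwidth > 0, slope > 0,
            adc_sample_rate > 0, adc_samples >= 2,
            n_tx >= 1, n_rx >= 1, frame_rate > 0, chirp_loops >= 1)
  # slope and ramp time must describe the same sweep
  if (abs(slope * ramp_end_time - bandwidth) / bandwidth > 1e-3)
    stop("slope * ramp_end_time disagrees with bandwidth by more than 0.1%")
  cfg <- list(
    start_frequency = start_frequency, bandwidth = bandwidth, slope = slope,
    adc_sample_rate = adc_sample_rate, adc_samples = as.integer(adc_samples),
    n_tx = as.integer(n_tx), n_rx = as.integer(n_rx),
    frame_rate = frame_rate, chirp_loops = as.integer(chirp_loops),
    idle_time = idle_time, adc_start_time = adc_start_time,
    ramp_end_time = ramp_end_time,
    n_virtual = as.integer(n_tx) * as.integer(n_rx),
    wavelength = SPEED_OF_LIGHT / start_frequency)
  class(cfg) <- "radar_config"
  cfg
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  f_c = %.2f GHz, B = %.2f MHz, S = %.3f MHz/us\n",
              x$start_frequency / 1e9, x$bandwidth / 1e6, x$slope / 1e12))
  cat(sprintf("  %d ADC samples @ %.2f MHz, %d virtual channels (%d Tx x %d Rx)\n",
              x$adc_samples, x$adc_sample_rate / 1e6, x$n_virtual, x$n_tx, x$n_rx))
  cat(sprintf("  frame rate %g Hz, lambda = %.4f mm, delta_r = %.4f m\n",
              x$frame_rate, x$wavelength * 1e3, range_resolution(x)))
  invisible(x)
}

#' Range resolution of a radar configuration
#'
#' The resolution is set by the bandwidth actually swept while the ADC
#' captures: `B_sampled = S * adc_samples / adc_sample_rate`, giving
#' `delta_r = c / (2 * B_sampled)`. For the default configuration this is
#' 0.0451 m.
#'
#' @param config A [radar_config()].
#' @return Range-bin size in meters.
#' @export
range_resolution <- function(config) {
  stopifnot(inherits(config, "radar_config"))
  b_sampled <- config$slope * (config$adc_samples / config$adc_sample_rate)
  SPEED_OF_LIGHT / (2 * b_sampled)
}

#' Convert a phase change to chest-wall displacement
#'
#' The slow-time phase of the IF signal moves by `4 * pi / lambda` radians per
#' meter of radial displacement, so `delta_d = lambda * delta_phi / (4 * pi)`.
#'
#' @param phase_delta Phase change in radians (vectorized).
#' @param config A [radar_config()] supplying the wavelength.
#' @return Displacement in meters.
#' @export
phase_to_displacement <- function(phase_delta, config) {
  stopifnot(inherits(config, "radar_config"))
  config$wavelength * phase_delta / (4 * pi)
}

# Maximum unambiguous IF range given the ADC rate (complex sampling:
# f_IF must stay below the sample rate / 2 guard used by the simulator).
max_unambiguous_range <- function(config) {
  (config$adc_sample_rate / 2) * SPEED_OF_LIGHT / (2 * config$slope)
}
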