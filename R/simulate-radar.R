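#' Chest-wall motion model
#'
#' Parametric model of the radial chest position seen by the radar:
#' a baseline range plus sinusoidal respiration (with optional harmonics),
#' a sinusoidal heartbeat component, and optional step/ramp motion artifacts.
#'
#' @param baseline_range Resting chest range R0 in meters.
#' @param resp_rate Respiration rate in Hz, in (0, 0.5].
#' @param resp_amplitude Respiration displacement amplitude in meters
#'   (typically 1-5 mm).
#' @param heart_rate Heart rate in Hz, in (0.5, 3).
#' @param heart_amplitude Heartbeat displacement amplitude in meters
#'   (typically 0.05-0.3 mm).
#' @param resp_harmonics List of `c(multiple, relative_amplitude)` pairs added
#'   to the respiration fundamental. Default: one 2nd harmonic at 20%.
#' @param motion_artifacts List of `c(start_s, duration_s, displacement_m)`
#'   ramp events (linear onset over `duration`, then sustained), default none.
#' @param resp_phase,heart_phase Onset phases of the respiration and
#'   heartbeat components in radians: the recording start is arbitrary
#'   relative to both physiological cycles, so realistic cohorts draw these
#'   uniformly on `[0, 2*pi)`.
#' @return A `chest_motion` object.
#' @export
chest_motion <- function(baseline_range = 0.7,
                         resp_rate = 0.25, resp_amplitude = 3e-3,
                         heart_rate = 1.2, heart_amplitude = 1e-4,
                         resp_harmonics = list(c(2, 0.2)),
                         motion_artifacts = list(),
                         resp_phase = 0, heart_phase = 0) {
  stopifnot(resp_rate > 0, resp_rate <= 0.5,
            heart_rate > 0.5, heart_rate < 3,
            resp_amplitude > 0, heart_amplitude > 0, baseline_range > 0)
  structure(list(baseline_range = baseline_range,
                 resp_rate = resp_rate, resp_amplitude = resp_amplitude,
                 heart_rate = heart_rate, heart_amplitude = heart_amplitude,
                 resp_harmonics = resp_harmonics,
                 motion_artifacts = motion_artifacts,
                 resp_phase = resp_phase, heart_phase = heart_phase),
            class = "chest_motion")
}

#' Evaluate chest range over time
#'
#' @param motion A [chest_motion()].
#' @param t Time points in seconds.
#' @return Radial range R(t) in meters.
#' @export
chest_range <- function(motion, t) {
  r <- motion$baseline_range +
    motion$resp_amplitude * sin(2 * pi * motion$resp_rate * t + motion$resp_phase) +
    motion$heart_amplitude * sin(2 * pi * motion$heart_rate * t + motion$heart_phase)
  for (h in motion$resp_harmonics) {
    r <- r + motion$resp_amplitude * h[2] *
      sin(2 * pi * motion$resp_rate * h[1] * t + h[1] * motion$resp_phase)
  }
  for (a in motion$motion_artifacts) {
    ramp <- pmin(pmax((t - a[1]) / max(a[2], 1e-9), 0), 1)
    r <- r + a[3] * ramp
  }
  r
}

#' Radar scene model
#'
#' A scene is one breathing target plus static clutter reflectors (walls,
#' furniture) and complex receiver noise. Channel noise realizations are
#' independent; the target return is identical across virtual channels.
#'
#' @param target A [chest_motion()], or `NULL` for a clutter-only scene.
#' @param clutter List of `c(range_m, relative_amplitude)` static reflectors.
#' @param noise_sd Per-sample complex noise SD relative to the unit target
#'   amplitude (SD of each of the real/imaginary parts). Default 1: raw-ADC
#'   noise power on par with the target return, a conservative setting for a
#'   consumer radar at under a meter.
#' @param seed Integer seed; identical seeds give bit-identical cubes.
#' @return A `scene_model` object.
#' @export
scene_model <- function(target = chest_motion(),
                        clutter = list(c(1.5, 2), c(2.5, 1)),
                        noise_sd = 1, seed = 1L) {
  stopifnot(is.null(target) || inherits(target, "chest_motion"),
            noise_sd >= 0)
  for (cl in clutter) stopifnot(length(cl) == 2, cl[1] > 0, cl[2] >= 0)
  structure(list(target = target, clutter = clutter,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_model")
}

#' Simulate a raw FMCW ADC cube
#'
#' Generates the complex raw-ADC data cube for a scene under the stop-and-hop
#' approximation: the chest range is evaluated once per chirp (slow time), and
#' each reflector contributes a fast-time beat tone
#' `A * exp(1i * (2*pi*f_IF*t_fast + 4*pi*R(t_slow)/lambda))` per chirp.
#' The beat frequency of each reflector is fixed at its baseline range
#' (`f_IF = S * 2 * R0 / c`): mm-scale chest displacement cannot move the beat
#' tone by a resolvable fraction of a range bin, while its full effect on the
#' phase term is retained. Independent complex Gaussian noise is added per
#' channel.
#'
#' @param config A [radar_config()].
#' @param scene A [scene_model()].
#' @param duration Recording length in seconds (>= 1).
#' @return An `adc_cube`: complex array `[n_virtual, adc_samples, n_chirps]`
#'   with the config attached as attribute `config`.
#' @export
simulate_adc_cube <- function(config, scene, duration) {
  stopifnot(inherits(config, "radar_config"), inherits(scene, "scene_model"),
            duration >= 1)
  ranges0 <- c(if (!is.null(scene$target)) scene$target$baseline_range,
               vapply(scene$clutter, `[`, numeric(1), 1))
  if (length(ranges0) == 0) stop("scene contains no reflectors")
  if (any(2 * config$slope * ranges0 / SPEED_OF_LIGHT >
          config$adc_sample_rate / 2))
    stop("reflector beat frequency exceeds half the ADC sample rate (aliased)")

  n_fast <- config$adc_samples
  n_chirp <- as.integer(round(config$frame_rate * duration)) * config$chirp_loops
  t_fast <- (seq_len(n_fast) - 1) / config$adc_sample_rate
  t_slow <- (seq_len(n_chirp) - 1) / config$frame_rate

  lam <- config$wavelength
  base <- matrix(0i, n_fast, n_chirp)
  if (!is.null(scene$target)) {
    # target: rank-1 structure, outer(fast-time tone, slow-time phasor)
    f_if_t <- config$slope * 2 * scene$target$baseline_range / SPEED_OF_LIGHT
    r_t <- chest_range(scene$target, t_slow)
    base <- base + outer(exp(1i * 2 * pi * f_if_t * t_fast),
                         exp(1i * 4 * pi * r_t / lam))
  }
  for (cl in scene$clutter) {
    f_if_c <- config$slope * 2 * cl[1] / SPEED_OF_LIGHT
    base <- base + cl[2] * outer(exp(1i * 2 * pi * f_if_c * t_fast),
                                 rep(exp(1i * 4 * pi * cl[1] / lam), n_chirp))
  }

  # assemble channel-last for contiguous writes, then permute to the
  # channels x fast x slow layout of the on-disk format
  arr <- array(0i, dim = c(n_fast, n_chirp, config$n_virtual))
  set.seed(scene$seed)
  n <- n_fast * n_chirp
  for (ch in seq_len(config$n_virtual)) {
    sig <- base
    if (scene$noise_sd > 0)
      sig <- sig + complex(real = rnorm(n, sd = scene$noise_sd),
                           imaginary = rnorm(n, sd = scene$noise_sd))
    arr[, , ch] <- sig
  }
  structure(aperm(arr, c(3, 1, 2)), config = config,
            class = c("adc_cube", "array"))
}
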