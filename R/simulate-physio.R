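# Fixed two-lobe pulse shape: systolic peak + dicrotic bump, expressed as
# Gaussian lobes at fractions of the beat interval. Morphology is constant;
# only rate and jitter vary between simulations.
ppg_beat_lobes <- list(systolic = c(center = 0.30, width = 0.10, amp = 1.0),
                       dicrotic = c(center = 0.65, width = 0.15, amp = 0.30))

#' Simulate a PPG signal
#'
#' Quasi-periodic pulse train: each beat is a fixed two-lobe template
#' (systolic peak plus dicrotic bump) scaled to the beat interval; successive
#' intervals are `1/heart_rate` perturbed by Gaussian jitter; white noise is
#' added on top. Ground-truth systolic peak times are attached as attribute
#' `beat_times` for validation against detectors.
#'
#' @param heart_rate Mean beat rate in Hz.
#' @param rate_jitter SD of the relative beat-interval perturbation (fraction).
#' @param fs Sampling rate in Hz (>= 50).
#' @param duration Record length in seconds.
#' @param noise_sd Additive white-noise SD in signal units (template peak = 1).
#' @param seed Integer seed; identical seeds give identical signals.
#' @return A [physio_signal()] in `"a.u."` with attribute `beat_times` (s).
#' @export
simulate_ppg <- function(heart_rate = 1.2, rate_jitter = 0.03, fs = 200,
                         duration = 60, noise_sd = 0.02, seed = 1L) {
  stopifnot(fs >= 50, heart_rate > 0, rate_jitter >= 0, duration > 0)
  set.seed(as.integer(seed))
  mean_ivl <- 1 / heart_rate
  onsets <- numeric(0)
  t0 <- 0
  while (t0 < duration + mean_ivl) {
    onsets <- c(onsets, t0)
    ivl <- mean_ivl * (1 + rate_jitter * rnorm(1))
    t0 <- t0 + max(ivl, 0.3 * mean_ivl)
  }
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  beat_times <- numeric(0)
  for (i in seq_along(onsets)) {
    ivl <- if (i < length(onsets)) onsets[i + 1] - onsets[i] else mean_ivl
    for (lobe in ppg_beat_lobes) {
      ctr <- onsets[i] + lobe["center"] * ivl
      x <- x + lobe["amp"] * exp(-0.5 * ((t - ctr) / (lobe["width"] * ivl))^2)
    }
    sys_t <- onsets[i] + ppg_beat_lobes$systolic["center"] * ivl
    if (sys_t >= 0 && sys_t < duration) beat_times <- c(beat_times, sys_t)
  }
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  out <- physio_signal(x, fs, "a.u.")
  attr(out, "beat_times") <- unname(beat_times)
  out
}

# Unit bi-exponential skin-conductance-response kernel and its peak value.
scr_kernel <- function(t, rise, decay) {
  ifelse(t >= 0, exp(-t / decay) - exp(-t / rise), 0)
}

#' Peak of the unit bi-exponential SCR kernel
#'
#' Closed form: the kernel `exp(-t/decay) - exp(-t/rise)` peaks at
#' `t* = rise*decay/(decay-rise) * log(decay/rise)`.
#'
#' @param rise,decay Rise and decay time constants in seconds (`decay > rise`).
#' @return The kernel's maximum value (dimensionless, < 1).
#' @export
scr_kernel_peak <- function(rise, decay) {
  stopifnot(decay > rise, rise > 0)
  t_star <- rise * decay / (decay - rise) * log(decay / rise)
  scr_kernel(t_star, rise, decay)
}

#' Simulate a GSR (electrodermal) signal
#'
#' Builds a skin-conductance trace as a tonic level plus bi-exponential
#' phasic responses plus white noise, then converts to the resistance the
#' sensor reports (`kOhm = 1000 / uS`), clipped to the device's 100-2500 kOhm
#' measurement range.
#'
#' @param tonic_kohm Tonic resistance level in kOhm, within [100, 2500].
#' @param scr_events List of `c(onset_s, amplitude_uS, rise_s, decay_s)`
#'   phasic responses.
#' @param fs Sampling rate in Hz.
#' @param duration Record length in seconds.
#' @param noise_sd Conductance noise SD in uS.
#' @param seed Integer seed.
#' @return A [physio_signal()] in `"kOhm"`.
#' @export
simulate_gsr <- function(tonic_kohm = 500,
                         scr_events = list(c(10, 0.5, 1, 4), c(35, 0.8, 1, 4)),
                         fs = 200, duration = 60, noise_sd = 0.01, seed = 1L) {
  stopifnot(tonic_kohm >= 100, tonic_kohm <= 2500, fs > 0, duration > 0)
  set.seed(as.integer(seed))
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  g <- rep(1000 / tonic_kohm, n)
  for (ev in scr_events) {
    stopifnot(length(ev) == 4)
    g <- g + ev[2] * scr_kernel(t - ev[1], ev[3], ev[4])
  }
  if (noise_sd > 0) g <- g + rnorm(n, sd = noise_sd)
  r <- pmin(pmax(1000 / pmax(g, 1e-9), 100), 2500)
  physio_signal(r, fs, "kOhm")
}

#' Specification for a synthetic self-assessment cohort
#'
#' Per-clip population means and SDs of valence, arousal and dominance on the
#' 1-9 SAM scale, from which integer ratings are drawn as rounded, clipped
#' normals.
#'
#' @param n_participants Cohort size.
#' @param clip_means,clip_sds Numeric matrices `[n_clips, 3]` with columns
#'   valence, arousal, dominance. Defaults: the shipped per-clip summary of
#'   the 18 study stimuli (see [clip_rating_summary()]).
#' @param seed Integer seed.
#' @return A `sam_generator_spec` object.
#' @export
sam_generator_spec <- function(n_participants = 15,
                               clip_means = NULL, clip_sds = NULL,
                               seed = 1L) {
  if (is.null(clip_means) || is.null(clip_sds)) {
    summ <- clip_rating_summary()
    clip_means <- as.matrix(summ[, c("valence_mean", "arousal_mean", "dominance_mean")])
    clip_sds <- as.matrix(summ[, c("valence_sd", "arousal_sd", "dominance_sd")])
  }
  stopifnot(n_participants >= 1, all(dim(clip_means) == dim(clip_sds)),
            ncol(clip_means) == 3,
            all(clip_means >= 1), all(clip_means <= 9), all(clip_sds >= 0))
  structure(list(n_participants = as.integer(n_participants),
                 clip_means = unname(clip_means), clip_sds = unname(clip_sds),
                 seed = as.integer(seed)),
            class = "sam_generator_spec")
}

#' Simulate a cohort of SAM rating tables
#'
#' Draws integer 1-9 ratings for every participant x clip x scale from
#' normals with the per-clip means/SDs of the spec, rounded and clipped.
#'
#' @param spec A [sam_generator_spec()].
#' @return A data.frame with columns `participant`, `clip_id`, `valence`,
#'   `arousal`, `dominance`; one row per participant-clip.
#' @export
simulate_sam_ratings <- function(spec) {
  stopifnot(inherits(spec, "sam_generator_spec"))
  set.seed(spec$seed)
  n_clip <- nrow(spec$clip_means)
  out <- expand.grid(clip_id = seq_len(n_clip),
                     participant = seq_len(spec$n_participants))
  out <- out[, c("participant", "clip_id")]
  for (j in 1:3) {
    raw <- rnorm(nrow(out),
                 mean = spec$clip_means[out$clip_id, j],
                 sd = spec$clip_sds[out$clip_id, j])
    out[[c("valence", "arousal", "dominance")[j]]] <-
      as.integer(pmin(pmax(round(raw), 1), 9))
  }
  rownames(out) <- NULL
  out
}

#' Per-clip rating summary of the 18 study stimuli
#'
#' Mean and SD of valence, arousal and dominance ratings for each film clip,
#' as reported in the dataset's stimulus validation. Used as the default
#' population for the synthetic rating generator and by the rating-consistency
#' statistics.
#'
#' @return A data.frame of 18 rows: `clip_id`, `{scale}_mean`, `{scale}_sd`.
#' @export
clip_rating_summary <- function() {
  path <- system.file("extdata", "clip_rating_summary.csv", package = "emowave")
  if (!nzchar(path)) stop("clip_rating_summary.csv not found")
  utils::read.csv(path)
}
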