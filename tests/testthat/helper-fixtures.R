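# Shared fixtures: a scaled-down radar configuration for oracle tests (small
# enough for brute-force DFT comparison) and tiny scene builders. All data is
# generated in code at test time.

small_config <- function(adc_samples = 64, n_tx = 1, n_rx = 2,
                         frame_rate = 20) {
  radar_config(adc_samples = adc_samples, n_tx = n_tx, n_rx = n_rx,
               frame_rate = frame_rate)
}

# noiseless single-target scene at the default 0.7 m
quiet_scene <- function(motion = chest_motion(), clutter = list()) {
  scene_model(target = motion, clutter = clutter, noise_sd = 0)
}

# brute-force O(N^2) DFT of a vector (independent oracle for range_fft)
naive_dft <- function(x) {
  n <- length(x)
  vapply(seq_len(n) - 1, function(k) {
    sum(x * exp(-2i * pi * k * (seq_len(n) - 1) / n))
  }, complex(1))
}

# a hand-built range-time matrix with prescribed per-bin constant magnitudes
flat_rtm <- function(magnitudes, n_chirp = 10, range_bin_size = 0.05,
                     slow_time_rate = 100) {
  m <- matrix(complex(modulus = rep(magnitudes, n_chirp),
                      argument = 0), length(magnitudes), n_chirp)
  structure(m, range_bin_size = range_bin_size,
            slow_time_rate = slow_time_rate,
            class = c("range_time_matrix", "matrix"))
}

# build per-trial feature matrices from two Gaussian blobs
blob_trials <- function(n_trials, n_windows = 12, d = 6, sep = 0,
                        seed = 1) {
  set.seed(seed)
  labels <- rep(c("low", "high"), length.out = n_trials)
  feats <- lapply(seq_len(n_trials), function(i) {
    mu <- if (labels[i] == "high") sep else -sep
    matrix(rnorm(n_windows * d, mean = mu), n_windows, d)
  })
  names(feats) <- sprintf("T%02d", seq_len(n_trials))
  list(features = feats, labels = labels)
}
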