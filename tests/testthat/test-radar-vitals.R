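test_that("range FFT agrees with a brute-force DFT on small cubes", {
  cfg <- small_config(adc_samples = 64)
  scene <- scene_model(target = chest_motion(), noise_sd = 1, seed = 5)
  cube <- simulate_adc_cube(cfg, scene, 1)
  rtms <- range_fft(cube, cfg)
  for (ch in 1:2) {
    for (j in c(1, 7, 20)) {
      oracle <- naive_dft(cube[ch, , j])
      expect_lt(max(Mod(rtms[[ch]][, j] - oracle)) / max(Mod(oracle)), 1e-9)
    }
  }
})

test_that("the strongest bin sits at the reflector's range", {
  cfg <- radar_config()
  cube <- simulate_adc_cube(cfg, quiet_scene(), 1)
  rtm <- range_fft(cube, cfg)[[1]]
  expect_identical(which.max(rowMeans(Mod(rtm))) - 1L,
                   as.integer(round(0.7 / range_resolution(cfg))))  # bin 16

  # two well-separated reflectors produce two local maxima at their bins
  dr <- range_resolution(cfg)
  scene2 <- scene_model(target = NULL,
                        clutter = list(c(10 * dr, 1), c(20 * dr, 1)),
                        noise_sd = 0)
  rtm2 <- range_fft(simulate_adc_cube(cfg, scene2, 1), cfg)[[1]]
  amp <- rowMeans(Mod(rtm2))
  for (b in c(10, 20)) {
    expect_gt(amp[b + 1], amp[b])       # 0-based bin b vs neighbors
    expect_gt(amp[b + 1], amp[b + 2])
  }
})

test_that("range FFT and MTI are linear and preserve structure", {
  cfg <- small_config(adc_samples = 32)
  s1 <- scene_model(target = chest_motion(), noise_sd = 0.5, seed = 1)
  s2 <- scene_model(target = NULL, clutter = list(c(0.9, 2)),
                    noise_sd = 0.5, seed = 2)
  a <- simulate_adc_cube(cfg, s1, 1)
  b <- simulate_adc_cube(cfg, s2, 1)
  ab <- unclass(a) + unclass(b)
  attr(ab, "config") <- cfg
  class(ab) <- class(a)
  r_ab <- range_fft(ab, cfg)[[1]]
  r_sum <- range_fft(a, cfg)[[1]] + range_fft(b, cfg)[[1]]
  expect_lt(max(Mod(r_ab - r_sum)), 1e-9 * max(Mod(r_ab)))

  # all-zero cube maps to an all-zero RTM
  z <- a; z[] <- 0i
  expect_true(all(range_fft(z, cfg)[[1]] == 0))
})

test_that("mean cancellation zeroes slow-time means and keeps variance", {
  cfg <- small_config()
  cube <- simulate_adc_cube(cfg, scene_model(seed = 3), 2)
  rtm <- range_fft(cube, cfg)[[1]]
  hat <- mti_mean_cancellation(rtm)
  expect_lt(max(Mod(rowMeans(hat))), 1e-12 * max(Mod(rtm)))
  # per-bin slow-time variance is mean-invariant
  v_before <- apply(rtm, 1, function(r) mean(Mod(r - mean(r))^2))
  v_after <- apply(hat, 1, function(r) mean(Mod(r - mean(r))^2))
  expect_equal(v_after, v_before, tolerance = 1e-12)

  # purely static scene collapses to ~0
  st <- simulate_adc_cube(cfg, scene_model(target = NULL,
                                           clutter = list(c(0.7, 1)),
                                           noise_sd = 0), 2)
  hat_st <- mti_mean_cancellation(range_fft(st, cfg)[[1]])
  expect_lt(max(Mod(hat_st)), 1e-9 * max(Mod(range_fft(st, cfg)[[1]])))

  expect_error(mti_mean_cancellation(flat_rtm(c(1, 2), n_chirp = 1)),
               "at least 2 chirps")
})

test_that("bin selection weights follow the amplitude normalization", {
  rtm <- flat_rtm(c(0.1, 2, 1, 1, 1, 1, 0.2, 0.1), range_bin_size = 0.2)
  sel <- select_bins(rtm, 5, search_window = c(0.1, 1.3))
  expect_equal(sum(sel$weights), 1)
  expect_true(all(sel$weights >= 0))
  expect_equal(sel$weights, c(1 / 3, 1 / 6, 1 / 6, 1 / 6, 1 / 6))
  expect_identical(sel$bin_indices[1], 1L)          # the amplitude-2 bin
  # ties broken toward the lower bin index
  expect_identical(sel$bin_indices[-1], c(2L, 3L, 4L, 5L))

  expect_error(select_bins(rtm, 5, search_window = c(10, 20)),
               "outside the RTM")
  expect_error(select_bins(rtm, 6, search_window = c(0.1, 1.1)),
               "fewer than k bins")
})

test_that("selected bins cluster around a simulated target", {
  cfg <- radar_config()
  cube <- simulate_adc_cube(cfg, scene_model(seed = 9), 5)
  rtm <- mti_mean_cancellation(range_fft(cube, cfg)[[1]])
  sel <- select_bins(rtm, 5, search_window = c(0.3, 1.5))
  expect_true(all(abs(sel$bin_indices - 16) <= 2))
})

test_that("phase unwrapping restores continuity", {
  out <- unwrap_phase(c(3.0, -3.0))
  expect_equal(out, c(3.0, 3.0 + (2 * pi - 6.0)))
  expect_equal(round(out[2], 5), 3.28319)

  smooth <- cumsum(runif(50, -1, 1))
  expect_identical(unwrap_phase(smooth), smooth)

  # linear motion: wrapped 4*pi*(R0 + v t)/lambda unwraps to the ramp
  lam <- 5e-3
  t <- seq(0, 5, by = 0.01)
  truth <- 4 * pi * (0.7 + 0.02 * t) / lam
  wrapped <- Arg(exp(1i * truth))
  rec <- unwrap_phase(wrapped)
  expect_lt(max(abs((rec - rec[1]) - (truth - truth[1]))), 1e-9)
})

test_that("phase fusion is exact for coherent bins", {
  # single bin with weight 1: identity
  cfg <- small_config()
  cube <- simulate_adc_cube(cfg, quiet_scene(), 10)
  rtm <- range_fft(cube, cfg)[[1]]
  sel1 <- select_bins(rtm, 1)
  expect_equal(fuse_phase(rtm, sel1),
               unwrap_phase(Arg(rtm[sel1$bin_indices + 1, ])))

  # identical phase across bins: any weights return that series
  sel5 <- select_bins(rtm, 5)
  ph5 <- fuse_phase(rtm, sel5)
  ph1 <- fuse_phase(rtm, sel1)
  expect_equal(ph5 - ph5[1], ph1 - ph1[1], tolerance = 1e-9)
})

test_that("fused phase reproduces the chest trajectory to numerical precision", {
  cfg <- radar_config()
  motion <- chest_motion()
  cube <- simulate_adc_cube(cfg, quiet_scene(motion), 10)
  rtm <- range_fft(cube, cfg)[[1]]
  ph <- fuse_phase(rtm, select_bins(rtm, 5))
  truth <- 4 * pi * chest_range(motion, (0:999) / cfg$frame_rate) /
    cfg$wavelength
  dev <- ph - truth
  expect_lt(max(abs(dev - mean(dev))), 1e-6)
})

test_that("zero-magnitude bins are dropped and weights renormalized", {
  rtm <- flat_rtm(c(1, 1, 1), n_chirp = 8, range_bin_size = 0.05)
  rtm[2, 3] <- 0i
  sel <- structure(list(bin_indices = c(0L, 1L, 2L),
                        mean_amplitudes = c(1, 1, 1),
                        weights = c(1, 1, 1) / 3),
                   class = "bin_selection")
  expect_warning(ph <- fuse_phase(rtm, sel), "dropped")
  expect_equal(ph, rep(0, 8))
})

test_that("the extraction chain recovers simulated vital rates", {
  cfg <- radar_config()
  scene <- scene_model(target = chest_motion(resp_rate = 0.25,
                                             heart_rate = 1.2),
                       seed = 21)
  cube <- simulate_adc_cube(cfg, scene, 60)
  vs <- extract_vital_sign(cube, cfg)
  expect_length(vs$fused_phase, 6000)
  expect_length(vs$vital_sign, 5999)
  expect_length(vs$respiration, 5999)
  bin <- 1 / 60   # spectral bin of a 60 s record
  expect_lt(abs(dominant_frequency(vs$respiration, 100, c(0.05, 0.55)) - 0.25),
            bin)
  expect_lt(abs(dominant_frequency(vs$heartbeat, 100, c(0.8, 2.0)) - 1.2),
            bin)
})

test_that("channel averaging is idempotent over identical channels", {
  cfg12 <- radar_config(n_tx = 2, n_rx = 2)
  cube <- simulate_adc_cube(cfg12, quiet_scene(), 12)   # noiseless: identical
  vs4 <- extract_vital_sign(cube, cfg12)
  cfg1 <- radar_config(n_tx = 1, n_rx = 1)
  one <- unclass(cube)[1, , , drop = FALSE]
  attr(one, "config") <- cfg1
  class(one) <- c("adc_cube", "array")
  vs1 <- extract_vital_sign(one, cfg1)
  expect_equal(vs4$fused_phase, vs1$fused_phase, tolerance = 1e-12)
})

test_that("the heartbeat filter rejects pure respiration-band modulation", {
  # stop-band attenuation of the designed band-pass pair on a pure 0.25 Hz
  # vital-sign component
  fs <- 100
  vital <- sin(2 * pi * 0.25 * (0:2999) / fs)
  resp <- emowave:::butter_filtfilt(vital, 4, c(0.1, 0.5), "pass", fs)
  heart <- emowave:::butter_filtfilt(vital, 6, c(1.0, 1.8), "pass", fs)
  expect_lt(sqrt(mean(heart^2)), 0.05 * sqrt(mean(resp^2)))
})
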