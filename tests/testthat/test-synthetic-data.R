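test_that("a static scene yields identical chirps and constant slow-time phase", {
  cfg <- small_config()
  scene <- scene_model(target = NULL, clutter = list(c(0.7, 1)),
                       noise_sd = 0, seed = 7)
  cube <- simulate_adc_cube(cfg, scene, 2)
  # every chirp identical
  first <- cube[1, , 1]
  for (j in c(2, 10, 40)) expect_equal(cube[1, , j], first)
  # slow-time phase at the dominant bin is constant
  rtm <- range_fft(cube, cfg)[[1]]
  b <- which.max(rowMeans(Mod(rtm)))
  expect_lt(max(abs(diff(Arg(rtm[b, ])))), 1e-10)
})

test_that("heartbeat displacement maps to the predicted phase excursion", {
  # 1 mm amplitude at 60 GHz: peak-to-peak phase 2 * 4*pi*d / lambda
  cfg <- small_config()
  motion <- chest_motion(resp_amplitude = 1e-12, heart_amplitude = 1e-3,
                         heart_rate = 1.2, resp_harmonics = list())
  cube <- simulate_adc_cube(small_config(frame_rate = 100), quiet_scene(motion), 10)
  rtm <- range_fft(cube, small_config(frame_rate = 100))[[1]]
  sel <- select_bins(rtm, 1)
  ph <- fuse_phase(rtm, sel)
  expected_ptp <- 2 * 4 * pi * 1e-3 / cfg$wavelength   # ~5.03 rad
  # slow-time sampling does not land exactly on the sinusoid extrema
  expect_equal(max(ph) - min(ph), expected_ptp, tolerance = 5e-3)
})

test_that("aliased reflectors are rejected", {
  cfg <- small_config()
  too_far <- (cfg$adc_sample_rate / 2) * 3e8 / (2 * cfg$slope) + 1
  expect_error(
    simulate_adc_cube(cfg, scene_model(target = NULL,
                                       clutter = list(c(too_far, 1))), 1),
    "aliased")
})

test_that("all four generators are bit-reproducible under a fixed seed", {
  cfg <- small_config()
  scene <- scene_model(seed = 42)
  expect_identical(simulate_adc_cube(cfg, scene, 1),
                   simulate_adc_cube(cfg, scene, 1))
  expect_identical(simulate_ppg(seed = 42), simulate_ppg(seed = 42))
  expect_identical(simulate_gsr(seed = 42), simulate_gsr(seed = 42))
  spec <- sam_generator_spec(seed = 42)
  expect_identical(simulate_sam_ratings(spec), simulate_sam_ratings(spec))
})

test_that("clean PPG is periodic at the requested rate and band-limited", {
  ppg <- simulate_ppg(heart_rate = 1.2, rate_jitter = 0, noise_sd = 0,
                      fs = 200, duration = 60)
  f <- dominant_frequency(ppg$samples, 200, c(0.5, 3))
  expect_equal(f, 1.2, tolerance = 0.01)
  # pulse template carries essentially no energy above 15 Hz
  expect_gt(snr_db(ppg, 15), 30)
})

test_that("GSR construction matches the bi-exponential closed form", {
  # no events, no noise: constant resistance at the tonic level
  flat <- simulate_gsr(tonic_kohm = 500, scr_events = list(), noise_sd = 0)
  expect_true(all(flat$samples == 500))
  expect_identical(flat$unit, "kOhm")

  # one event: conductance peak = tonic conductance + a * kernel peak
  a <- 0.8
  g1 <- simulate_gsr(tonic_kohm = 500, scr_events = list(c(5, a, 1, 4)),
                     noise_sd = 0, duration = 40)
  peak_cond <- max(resistance_to_conductance(g1$samples))
  expect_equal(peak_cond, 1000 / 500 + a * scr_kernel_peak(1, 4),
               tolerance = 1e-3)

  # processed conductance tracks the noise-free conductance
  proc <- process_gsr(g1)
  truth <- resistance_to_conductance(g1$samples)
  core <- 200:7800   # away from filter edges
  expect_lt(max(abs(proc$samples[core] - truth[core])), 0.05)
})

test_that("synthetic ratings reproduce the requested population structure", {
  means <- matrix(c(6.4, 3.2, 5.0), 1)   # one clip, V/A/D
  # zero SD: every participant reports the rounded mean
  s0 <- sam_generator_spec(n_participants = 10, clip_means = means,
                           clip_sds = matrix(0, 1, 3), seed = 1)
  r0 <- simulate_sam_ratings(s0)
  expect_true(all(r0$valence == 6L))
  expect_true(all(r0$arousal == 3L))
  expect_true(all(r0$dominance == 5L))

  # large cohort: empirical means within 3*SD/sqrt(n) of the population
  summ <- clip_rating_summary()
  n <- 600
  sp <- sam_generator_spec(n_participants = n, seed = 3)
  r <- simulate_sam_ratings(sp)
  emp <- tapply(r$valence, r$clip_id, mean)
  # rounding to integers adds at most a small bias; allow it on top of SE
  tol <- 3 * summ$valence_sd / sqrt(n) + 0.15
  expect_true(all(abs(emp - summ$valence_mean) < tol))

  # ratings are always integers in [1, 9]
  vals <- unlist(r[c("valence", "arousal", "dominance")])
  expect_true(all(vals == round(vals) & vals >= 1 & vals <= 9))
})

test_that("threshold-5 label counts follow the clipped-normal tail mass", {
  mu <- 6.0; sd <- 1.5; n <- 4000
  sp <- sam_generator_spec(n_participants = n,
                           clip_means = matrix(mu, 1, 3),
                           clip_sds = matrix(sd, 1, 3), seed = 11)
  labs <- binarize_labels(simulate_sam_ratings(sp))
  v <- labs[labs$scale == "valence", ]
  # P(round(X) > 5) = P(X > 5.5), P(round(X) < 5) = P(X < 4.5)
  p_high <- pnorm(5.5, mu, sd, lower.tail = FALSE)
  p_low <- pnorm(4.5, mu, sd)
  expect_equal(mean(v$label == "high"), p_high,
               tolerance = 4 * sqrt(p_high * (1 - p_high) / n) / p_high)
  expect_equal(mean(v$label == "low"), p_low,
               tolerance = 4 * sqrt(p_low * (1 - p_low) / n) / p_low)
})
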