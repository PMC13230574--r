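#!/usr/bin/env Rscript
# Simulates the synthetic study cohort used by the downstream analyses:
# per-trial scene parameters (chest motion, heart/respiration rates, seating
# distance), raw PPG/GSR recordings and SAM rating tables, plus one small
# raw-ADC MAT file demonstrating the on-disk radar format. Radar cubes for
# the full trials are large, so they are re-generated on the fly by
# 02_extract_vitals.R from the scene table written here.
#
# Outputs under results/synthetic_dataset/.

suppressMessages(library(emowave))

seed <- 20260928L
set.seed(seed)
root <- "results/synthetic_dataset"
n_participants <- 2
clips <- 1:3
trial_duration <- 70   # seconds; >= 60 s analysis tail plus lead-in

dir.create(root, recursive = TRUE, showWarnings = FALSE)

# per-trial physiological ground truth: rates within the study's adult range,
# seating distance within the 0.6-0.9 m setup span
scenes <- expand.grid(participant = seq_len(n_participants), clip = clips)
scenes$resp_rate <- round(runif(nrow(scenes), 0.18, 0.4), 3)
scenes$heart_rate <- round(runif(nrow(scenes), 1.0, 1.7), 3)
scenes$baseline_range <- round(runif(nrow(scenes), 0.6, 0.9), 3)
scenes$resp_phase <- round(runif(nrow(scenes), 0, 2 * pi), 3)
scenes$heart_phase <- round(runif(nrow(scenes), 0, 2 * pi), 3)
scenes$scene_seed <- sample.int(2^30, nrow(scenes))
scenes$duration <- trial_duration
write.csv(scenes, file.path(root, "scene_parameters.csv"), row.names = FALSE)

# raw physiology in the dataset's two-header-row CSV dialect
for (i in seq_len(nrow(scenes))) {
  p <- scenes$participant[i]; cl <- scenes$clip[i]
  ppg <- simulate_ppg(heart_rate = scenes$heart_rate[i], rate_jitter = 0.03,
                      duration = trial_duration,
                      seed = scenes$scene_seed[i] + 1L)
  gsr <- simulate_gsr(tonic_kohm = runif(1, 300, 900),
                      scr_events = list(c(12, 0.5, 1, 4), c(40, 0.9, 1, 5)),
                      duration = trial_duration,
                      seed = scenes$scene_seed[i] + 2L)
  path <- dataset_path(root, "ppg_and_gsr", p, cl)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_physio_csv(path, ppg, gsr)
}

# SAM ratings for a 15-participant cohort drawn from the study's per-clip
# rating distributions
sam <- simulate_sam_ratings(sam_generator_spec(n_participants = 15,
                                               seed = seed))
for (p in unique(sam$participant)) {
  path <- dataset_path(root, "sam", p)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_sam_csv(path, sam[sam$participant == p, ])
}

# one short raw-ADC file in the adcData MAT layout (kept small on purpose)
cfg <- radar_config()
demo_scene <- scene_model(target = chest_motion(
  baseline_range = scenes$baseline_range[1],
  resp_rate = scenes$resp_rate[1], heart_rate = scenes$heart_rate[1]),
  seed = scenes$scene_seed[1])
demo <- simulate_adc_cube(cfg, demo_scene, 2)
path <- dataset_path(root, "mmwave", 1, 1)
dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
write_adc_mat(path, demo)

cat(sprintf("wrote %d trials x (PPG+GSR), %d SAM tables and 1 demo adcData file under %s\n",
            nrow(scenes), length(unique(sam$participant)), root))
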