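#!/usr/bin/env Rscript
# Conditions the raw PPG and GSR recordings of the synthetic cohort exactly
# as the dataset's processed-data layer defines: PPG band-pass 0.6-5 Hz +
# linear detrend + 0.1 s moving average; GSR resistance -> conductance +
# 1 Hz low-pass. Writes the single-column processed CSVs.

suppressMessages(library(emowave))

root <- "results/synthetic_dataset"
scenes <- read.csv(file.path(root, "scene_parameters.csv"))

for (i in seq_len(nrow(scenes))) {
  p <- scenes$participant[i]; cl <- scenes$clip[i]
  raw <- read_physio_csv(dataset_path(root, "ppg_and_gsr", p, cl))
  ppg <- process_ppg(raw$ppg)
  gsr <- process_gsr(raw$gsr)
  for (kind in c("ppg", "gsr")) {
    path <- file.path(root, "processed", kind,
                      sprintf("%s_P%02d_%02d.csv", kind, p, cl))
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    write_single_column_csv(path, (if (kind == "ppg") ppg else gsr)$samples)
  }
}
cat(sprintf("processed %d PPG and %d GSR records under %s/processed\n",
            nrow(scenes), nrow(scenes), root))
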