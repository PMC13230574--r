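#!/usr/bin/env Rscript
# Subject-dependent RBF-SVM baseline on the synthetic cohort's PPG features:
# per trial, the first 75% of windows train and the rest test; features are
# Z-scored with training statistics; C and gamma are grid-searched over the
# 11 x 6 logarithmic grid by stratified 5-fold CV. With only a handful of
# trials per synthetic participant this demonstrates the harness rather than
# estimating a meaningful accuracy; labels come from the simulated SAM
# ratings.

suppressMessages(library(emowave))

root <- "results/synthetic_dataset"
scenes <- read.csv(file.path(root, "scene_parameters.csv"))
seed <- 7L

rows <- list()
for (p in unique(scenes$participant)) {
  sam <- read_sam_csv(dataset_path(root, "sam", p))
  sam$participant <- p
  labs <- binarize_labels(sam)
  for (sc in c("valence", "arousal", "dominance")) {
    clips <- scenes$clip[scenes$participant == p]
    feats <- lapply(clips, function(cl)
      read_feature_matrix(dataset_path(root, "ppgFea", p, cl)))
    names(feats) <- as.character(clips)
    lab <- labs$label[labs$scale == sc][match(clips, sam$clip_id)]
    keep <- lab != "excluded"
    if (length(unique(lab[keep])) < 2) {
      cat(sprintf("P%02d %s: single-class labels at this cohort size; skipped\n",
                  p, sc))
      next
    }
    rep <- classify_participant(feats[keep], lab[keep], seed = seed)
    rows[[length(rows) + 1]] <- data.frame(
      participant = p, scale = sc, accuracy = rep$accuracy,
      balanced_accuracy = rep$balanced_accuracy, f1 = rep$f1,
      c = rep$c, gamma = rep$gamma)
  }
}

if (length(rows)) {
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(root, "classification_metrics.csv"),
            row.names = FALSE)
  cat("\nper-participant metrics (PPG features):\n")
  print(tab, digits = 3)
  cat(sprintf("\nmean accuracy %.1f%%, balanced accuracy %.1f%%, F1 %.1f%%\n",
              mean(tab$accuracy), mean(tab$balanced_accuracy), mean(tab$f1)))
} else {
  cat("no participant had both classes among the labeled trials\n")
}
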