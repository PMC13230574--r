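#!/usr/bin/env Rscript
# Self-assessment statistics over the synthetic 15-participant SAM cohort:
# per-clip coefficient of variation, inter-scale and order correlations
# (tie-aware Spearman), valence-arousal quadrant assignment of the per-clip
# means, and the threshold-5 window-level class distribution.

suppressMessages(library(emowave))

root <- "results/synthetic_dataset"
sam <- do.call(rbind, lapply(1:15, function(p) {
  t <- read_sam_csv(dataset_path(root, "sam", p))
  t$participant <- p
  t
}))

# rating consistency
cs <- cv_summary(sam)
cv_tab <- data.frame(scale = names(cs$mean_cv), mean_cv = cs$mean_cv,
                     sd_cv = cs$sd_cv, row.names = NULL)
write.csv(cv_tab, file.path(root, "rating_cv.csv"), row.names = FALSE)
cat("per-scale mean (SD) of per-clip rating CVs:\n")
print(cv_tab, digits = 3)

# inter-scale correlations over all participant x clip ratings, plus a
# randomized display order (the synthetic cohort has no habituation, so the
# order column should be uncorrelated with every scale)
scales <- c("valence", "arousal", "dominance")
set.seed(99)
sam$order <- ave(sam$clip_id, sam$participant,
                 FUN = function(x) sample(seq_along(x)))
vars <- c(scales, "order")
rho <- outer(vars, vars, Vectorize(function(a, b)
  spearman_rho(sam[[a]], sam[[b]])))
dimnames(rho) <- list(vars, vars)
write.csv(round(rho, 3), file.path(root, "rating_correlations.csv"))
cat("\ntie-aware Spearman correlations (all individual ratings):\n")
print(round(rho, 2))

# quadrants of the per-clip mean ratings
means <- aggregate(cbind(valence, arousal) ~ clip_id, sam, mean)
means$quadrant <- mapply(quadrant, means$valence, means$arousal)
write.csv(means, file.path(root, "clip_quadrants.csv"), row.names = FALSE)
cat("\nquadrant occupancy of per-clip means:\n")
print(table(means$quadrant))

# threshold-5 labels and window-level class balance
dist <- class_distribution(binarize_labels(sam))
write.csv(dist, file.path(root, "class_distribution.csv"), row.names = FALSE)
cat("\nwindow-level class distribution (threshold 5, 12 windows/trial):\n")
print(dist, digits = 4)
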