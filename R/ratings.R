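#' Coefficient of variation
#'
#' Ratio of the sample (n-1) standard deviation to the mean.
#'
#' @param values Numeric vector of at least 2 values with non-zero mean.
#' @return CV (dimensionless).
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined")
  stats::sd(values) / m
}

#' Per-clip CV summary of a rating cohort
#'
#' Computes, for each clip and each scale, the coefficient of variation of
#' the participants' ratings, then the mean and SD of the per-clip CVs.
#' Accepts either a long rating table (from [simulate_sam_ratings()] /
#' [read_sam_csv()] rows bound together) or a moment summary with
#' `{scale}_mean` / `{scale}_sd` columns such as [clip_rating_summary()].
#'
#' @param ratings Data frame: either columns `clip_id`, `valence`, `arousal`,
#'   `dominance` (one row per participant-clip) or a per-clip moment summary.
#' @return A `cv_summary` list: `per_clip_cv` (matrix clips x 3), `mean_cv`
#'   and `sd_cv` (named length-3 vectors).
#' @export
cv_summary <- function(ratings) {
  scales <- c("valence", "arousal", "dominance")
  if (all(scales %in% names(ratings))) {
    per_clip <- sapply(scales, function(sc)
      tapply(ratings[[sc]], ratings$clip_id, coefficient_of_variation))
  } else if (all(paste0(scales, "_mean") %in% names(ratings))) {
    per_clip <- sapply(scales, function(sc)
      ratings[[paste0(sc, "_sd")]] / ratings[[paste0(sc, "_mean")]])
  } else stop("unrecognized ratings layout")
  per_clip <- as.matrix(per_clip)
  structure(list(per_clip_cv = per_clip,
                 mean_cv = colMeans(per_clip),
                 sd_cv = apply(per_clip, 2, stats::sd)),
            class = "cv_summary")
}

#' Tie-aware Spearman rank correlation
#'
#' Both lists are transformed to average ranks (ties share the mean of the
#' ranks they would occupy) and the Pearson correlation of the rank
#' variables is returned, handling the heavy ties of discrete rating scales
#' exactly.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  vx <- sum(dx^2); vy <- sum(dy^2)
  if (vx == 0 || vy == 0) stop("constant list: rank variance is zero")
  sum(dx * dy) / sqrt(vx * vy)
}

#' Two-sided t-based p-value for a Spearman correlation
#'
#' @param rho Correlation from [spearman_rho()].
#' @param n Number of paired observations.
#' @return p-value.
#' @export
spearman_pvalue <- function(rho, n) {
  stopifnot(n >= 3)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Valence-arousal quadrant of a rating pair
#'
#' Compares each coordinate with the scale center (default 5): arousal above
#' center is high arousal (HA), valence above center is high valence (HV);
#' coordinates equal to the center fall in the low half.
#'
#' @param valence,arousal Ratings in [1, 9].
#' @param center Scale midpoint (default 5).
#' @return One of `"LALV"`, `"LAHV"`, `"HALV"`, `"HAHV"`.
#' @export
quadrant <- function(valence, arousal, center = 5) {
  stopifnot(valence >= 1, valence <= 9, arousal >= 1, arousal <= 9)
  paste0(if (arousal > center) "HA" else "LA",
         if (valence > center) "HV" else "LV")
}

#' Binarize SAM ratings into low/high labels
#'
#' Ratings below the threshold are `"low"`, above it `"high"`, and ratings
#' exactly at the threshold are `"excluded"` from classification.
#'
#' @param sam Long rating table with columns `participant`, `clip_id`,
#'   `valence`, `arousal`, `dominance`.
#' @param threshold Rating threshold (default 5, the scale midpoint).
#' @return Long data frame with columns `participant`, `clip_id`, `scale`,
#'   `rating`, `label`.
#' @export
binarize_labels <- function(sam, threshold = 5) {
  scales <- c("valence", "arousal", "dominance")
  stopifnot(all(c("participant", "clip_id", scales) %in% names(sam)))
  out <- do.call(rbind, lapply(scales, function(sc) {
    r <- sam[[sc]]
    data.frame(participant = sam$participant, clip_id = sam$clip_id,
               scale = sc, rating = r,
               label = ifelse(r < threshold, "low",
                              ifelse(r > threshold, "high", "excluded")))
  }))
  rownames(out) <- NULL
  out
}

#' Window-level class distribution of binarized labels
#'
#' Each labeled (non-excluded) trial contributes `windows_per_clip`
#' window-level samples. Returns per-scale low/high/total counts and the
#' high-class percentage.
#'
#' @param labels Output of [binarize_labels()].
#' @param windows_per_clip Windows per trial (default 12).
#' @return Data frame with columns `scale`, `low`, `high`, `total`,
#'   `high_ratio` (percent; `NA` when no labeled trials exist).
#' @export
class_distribution <- function(labels, windows_per_clip = 12) {
  scales <- c("valence", "arousal", "dominance")
  out <- do.call(rbind, lapply(scales, function(sc) {
    l <- labels[labels$scale == sc, ]
    low <- sum(l$label == "low") * windows_per_clip
    high <- sum(l$label == "high") * windows_per_clip
    tot <- low + high
    data.frame(scale = sc, low = low, high = high, total = tot,
               high_ratio = if (tot > 0) 100 * high / tot else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
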