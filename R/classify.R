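#' Hyperparameter grid for the RBF-SVM baseline
#'
#' The geometric sequences with the stated endpoints and counts:
#' `C = 10^(-5..5)` (11 values) and `gamma = 10^(-4..1)` (6 values),
#' 66 candidate pairs in all.
#'
#' @return A `grid_spec` list with `c_values` and `gamma_values`.
#' @export
grid_spec <- function() {
  structure(list(c_values = 10^seq(-5, 5), gamma_values = 10^seq(-4, 1)),
            class = "grid_spec")
}

#' Chronological per-trial train/test split
#'
#' Within every labeled trial the first `ceiling(fraction * n)` windows (in
#' temporal order) go to the training set and the remainder to the test set
#' (12 windows -> 9 train / 3 test); trials labeled `"excluded"` are dropped.
#'
#' @param trial_features Named list of `windows x d` feature matrices, one
#'   per trial.
#' @param trial_labels Character vector (same length/order) of
#'   `"low"` / `"high"` / `"excluded"` labels.
#' @param fraction Training fraction in (0, 1), default 0.75.
#' @return A `split_dataset`: `train` and `test`, each a list with feature
#'   matrix `x`, label vector `y`, and `provenance` (trial, window index).
#' @export
split_by_trial <- function(trial_features, trial_labels, fraction = 0.75) {
  stopifnot(length(trial_features) == length(trial_labels),
            fraction > 0, fraction < 1)
  keep <- trial_labels != "excluded"
  trial_features <- trial_features[keep]
  trial_labels <- trial_labels[keep]
  acc <- list(train = NULL, test = NULL)
  for (set in c("train", "test"))
    acc[[set]] <- list(x = NULL, y = character(0),
                       provenance = data.frame(trial = character(0),
                                               window = integer(0)))
  for (i in seq_along(trial_features)) {
    m <- trial_features[[i]]
    n <- nrow(m)
    if (n < 4) stop("trial with fewer than 4 windows")
    n_train <- ceiling(fraction * n)
    if (n_train >= n) stop("empty test set for a trial")
    trial_id <- names(trial_features)[i]
    if (is.null(trial_id)) trial_id <- as.character(i)
    for (set in c("train", "test")) {
      rows <- if (set == "train") seq_len(n_train) else (n_train + 1):n
      acc[[set]]$x <- rbind(acc[[set]]$x, m[rows, , drop = FALSE])
      acc[[set]]$y <- c(acc[[set]]$y, rep(trial_labels[i], length(rows)))
      acc[[set]]$provenance <- rbind(acc[[set]]$provenance,
                                     data.frame(trial = trial_id,
                                                window = rows))
    }
  }
  structure(acc, class = "split_dataset")
}

#' Z-score standardization fitted on the training set
#'
#' Per feature, the mean and SD are computed across all training samples and
#' applied to both sets. Zero-SD (constant) features are mapped to 0 and
#' flagged. Test-set statistics never enter the transform.
#'
#' @param split A [split_by_trial()] result.
#' @return The split with standardized `x` matrices, plus `center`, `scale`
#'   and `constant_features` recorded.
#' @export
zscore_fit_apply <- function(split) {
  stopifnot(inherits(split, "split_dataset"), nrow(split$train$x) > 0)
  mu <- colMeans(split$train$x)
  sdv <- apply(split$train$x, 2, stats::sd)
  const <- sdv == 0
  sdv[const] <- 1
  for (set in c("train", "test")) {
    z <- sweep(sweep(split[[set]]$x, 2, mu), 2, sdv, "/")
    z[, const] <- 0
    split[[set]]$x <- z
  }
  split$center <- mu
  split$scale <- sdv
  split$constant_features <- const
  split
}

# deterministic stratified fold assignment
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Grid-searched RBF-SVM on a training set
#'
#' Evaluates every (C, gamma) pair of the grid by stratified k-fold
#' cross-validated accuracy on the training set, then refits the best pair
#' (ties resolved toward the first pair in grid order: C ascending outer,
#' gamma ascending inner) on the full training set. Deterministic under
#' `seed`.
#'
#' @param train_x Numeric feature matrix (already standardized).
#' @param train_y Label vector with both classes present.
#' @param grid A [grid_spec()].
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @return List with `model` (an [e1071::svm] fit), `c`, `gamma`, and
#'   `cv_accuracy` (matrix over the grid).
#' @export
grid_search_svm <- function(train_x, train_y, grid = grid_spec(),
                            cv_folds = 5, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  y <- factor(train_y)
  if (nlevels(y) < 2) stop("single-class training set")
  k <- min(cv_folds, min(table(y)))
  fold <- stratified_folds(y, k, seed)
  acc <- matrix(NA_real_, length(grid$c_values), length(grid$gamma_values),
                dimnames = list(C = grid$c_values, gamma = grid$gamma_values))
  for (ci in seq_along(grid$c_values)) {
    for (gi in seq_along(grid$gamma_values)) {
      hits <- 0
      for (f in seq_len(k)) {
        tr <- fold != f
        if (nlevels(droplevels(y[tr])) < 2) next
        fit <- e1071::svm(train_x[tr, , drop = FALSE], y[tr],
                          kernel = "radial", cost = grid$c_values[ci],
                          gamma = grid$gamma_values[gi], scale = FALSE)
        hits <- hits + sum(predict(fit, train_x[!tr, , drop = FALSE]) == y[!tr])
      }
      acc[ci, gi] <- hits / length(y)
    }
  }
  best <- which(acc == max(acc), arr.ind = TRUE)[1, ]
  model <- e1071::svm(train_x, y, kernel = "radial",
                      cost = grid$c_values[best[1]],
                      gamma = grid$gamma_values[best[2]], scale = FALSE)
  list(model = model, c = grid$c_values[best[1]],
       gamma = grid$gamma_values[best[2]], cv_accuracy = acc)
}

#' Evaluate a fitted classifier on a test set
#'
#' Reports accuracy, balanced accuracy (arithmetic mean of the per-class
#' recalls), the F1-score of the `"high"` class (harmonic mean of its
#' precision and recall) with macro-F1 alongside, per-class recalls and the
#' confusion counts. All rates are percentages.
#'
#' @param model A fitted [e1071::svm] model (or anything `predict`-able).
#' @param test_x Standardized test feature matrix.
#' @param test_y True labels.
#' @return An `eval_report` list.
#' @export
evaluate <- function(model, test_x, test_y) {
  stopifnot(nrow(test_x) > 0)
  pred <- as.character(predict(model, test_x))
  truth <- as.character(test_y)
  classes <- c("low", "high")
  conf <- table(factor(truth, classes), factor(pred, classes),
                dnn = c("truth", "pred"))
  recalls <- vapply(classes, function(cl) {
    n_cl <- sum(conf[cl, ])
    if (n_cl == 0) NA_real_ else conf[cl, cl] / n_cl
  }, numeric(1))
  f1_of <- function(cl) {
    tp <- conf[cl, cl]
    prec_den <- sum(conf[, cl]); rec_den <- sum(conf[cl, ])
    if (prec_den == 0 || rec_den == 0 || tp == 0) return(0)
    p <- tp / prec_den; r <- tp / rec_den
    2 * p * r / (p + r)
  }
  f1 <- vapply(classes, f1_of, numeric(1))
  structure(list(accuracy = 100 * mean(pred == truth),
                 balanced_accuracy = 100 * mean(recalls, na.rm = TRUE),
                 f1 = 100 * f1[["high"]],
                 macro_f1 = 100 * mean(f1),
                 recalls = 100 * recalls,
                 confusion = conf),
            class = "eval_report")
}

#' Subject-dependent classification for one participant and scale
#'
#' Convenience wrapper chaining [split_by_trial()], [zscore_fit_apply()],
#' [grid_search_svm()] and [evaluate()].
#'
#' @param trial_features Named list of per-trial feature matrices.
#' @param trial_labels `"low"` / `"high"` / `"excluded"` per trial.
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @return The [evaluate()] report, with the chosen `c` and `gamma` attached.
#' @export
classify_participant <- function(trial_features, trial_labels,
                                 grid = grid_spec(), seed = 1L) {
  split <- split_by_trial(trial_features, trial_labels)
  if (length(unique(split$train$y)) < 2) stop("single-class training set")
  split <- zscore_fit_apply(split)
  gs <- grid_search_svm(split$train$x, split$train$y, grid, seed = seed)
  rep <- evaluate(gs$model, split$test$x, split$test$y)
  rep$c <- gs$c
  rep$gamma <- gs$gamma
  rep
}
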