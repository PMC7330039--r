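#' Random-forest feature importance
#'
#' Fits a random-forest classifier on the training rows and returns the
#' impurity-decrease (information-gain) importances, normalized to sum to 1.
#' The forest used for importance is fixed (100 trees, default depth) rather
#' than tuned: stability of the importance estimate matters more here than
#' classification accuracy.
#'
#' @param train data.frame with a `label` factor column and feature columns
#'   (columns `gene` and `split` are ignored if present).
#' @param seed integer seed.
#' @param num_trees number of trees (default 100).
#' @return Named numeric importance vector, non-negative, summing to 1.
#' @export
rf_importance <- function(train, seed = 1L, num_trees = 100L) {
  if (nrow(train) == 0) stop_invalid("training data is empty")
  if (length(unique(train$label)) < 2) {
    stop_invalid("training data must contain both classes")
  }
  feats <- feature_columns(train)
  fit <- ranger::ranger(x = train[, feats, drop = FALSE],
                        y = factor(train$label),
                        num.trees = num_trees, importance = "impurity",
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  total <- sum(imp)
  if (total <= 0) rep(1 / length(imp), length(imp)) else imp / total
}

#' Label-permutation null distribution of feature importances
#'
#' Estimates the importance each feature would attain in a non-informative
#' setting: the class labels are shuffled uniformly `n_shuffles` times, the
#' forest is refit on each shuffle (with a fresh derived seed), and the
#' importances are recorded.
#'
#' @param train as in [rf_importance()].
#' @param n_shuffles number of label shuffles (default 100; at least 2 so the
#'   null SD is defined).
#' @param seed integer seed; shuffle permutations and forest seeds derive
#'   from it.
#' @param num_trees forest size per shuffle.
#' @return `n_shuffles` x n_features matrix of null importances.
#' @export
null_distribution <- function(train, n_shuffles = 100L, seed = 1L,
                              num_trees = 100L) {
  if (n_shuffles < 2) stop_invalid("n_shuffles must be >= 2 (null SD undefined)")
  feats <- feature_columns(train)
  out <- matrix(NA_real_, n_shuffles, length(feats),
                dimnames = list(NULL, feats))
  for (s in seq_len(n_shuffles)) {
    shuffled <- train
    shuffled$label <- with_seed(derive_seed(seed, "shuffle", s),
                                sample(train$label))
    out[s, ] <- rf_importance(shuffled, seed = derive_seed(seed, "importance", s),
                              num_trees = num_trees)
  }
  out
}

#' Importance z-scores against the permutation null
#'
#' `z = (real - mean(null)) / SD(null)` per feature. A degenerate null with
#' zero SD is mapped to a capped sentinel (+/-10 by the sign of the
#' deviation, 0 when the real importance equals the null mean), with a
#' warning.
#'
#' @param real named importance vector from the unshuffled model.
#' @param null_samples matrix from [null_distribution()] (columns = features).
#' @param cap magnitude used for the zero-SD sentinel (default 10).
#' @return Named numeric z-score vector.
#' @export
importance_zscores <- function(real, null_samples, cap = 10) {
  if (length(real) != ncol(null_samples)) {
    stop_invalid("real importances and null columns must agree")
  }
  mu <- colMeans(null_samples)
  sdev <- apply(null_samples, 2, sd)
  z <- (real - mu) / sdev
  degenerate <- sdev == 0
  if (any(degenerate)) {
    warning("zero null SD for ", sum(degenerate),
            " feature(s); z capped at +/-", cap)
    z[degenerate] <- sign(real[degenerate] - mu[degenerate]) * cap
  }
  z[!degenerate] <- pmin(pmax(z[!degenerate], -cap), cap)
  names(z) <- colnames(null_samples)
  z
}

#' Permutation-null feature importance over the ten negative sets
#'
#' For each dataset (one per negative set), fits the real forest on the
#' training split only, derives the label-shuffle null, and expresses the
#' real importance as a z-score against that null. Per-feature z-scores are
#' then averaged over the negative sets.
#'
#' @param datasets list of labeled datasets from [build_datasets()].
#' @param n_shuffles label shuffles per dataset (default 100).
#' @param seed master seed.
#' @param num_trees forest size (default 100).
#' @return Object of class `importance_report`: list with `z` (negative-set x
#'   feature z matrix), `real` (matrix of real importances), `avg_z` (named
#'   vector), `n_shuffles`.
#' @export
feature_importance_report <- function(datasets, n_shuffles = 100L, seed = 1L,
                                      num_trees = 100L) {
  feats <- feature_columns(datasets[[1]])
  zmat <- matrix(NA_real_, length(datasets), length(feats),
                 dimnames = list(NULL, feats))
  realmat <- zmat
  for (i in seq_along(datasets)) {
    train <- datasets[[i]][datasets[[i]]$split == "train", , drop = FALSE]
    real <- rf_importance(train, seed = derive_seed(seed, "importance", 1000 + i),
                          num_trees = num_trees)
    null <- null_distribution(train, n_shuffles = n_shuffles,
                              seed = derive_seed(seed, "shuffle", 1000 + i),
                              num_trees = num_trees)
    zmat[i, ] <- importance_zscores(real, null)
    realmat[i, ] <- real
  }
  structure(list(z = zmat, real = realmat, avg_z = colMeans(zmat),
                 n_shuffles = as.integer(n_shuffles)),
            class = "importance_report")
}

#' Select features by average permutation-null z-score
#'
#' Retains every feature whose z-score, averaged over the negative sets, is
#' at least `threshold` (boundary inclusive).
#'
#' @param report an `importance_report` (or a named average-z vector).
#' @param threshold selection threshold (default 0.5).
#' @return Character vector of retained feature names.
#' @export
select_features <- function(report, threshold = 0.5) {
  avg_z <- if (inherits(report, "importance_report")) report$avg_z else report
  keep <- names(avg_z)[avg_z >= threshold]
  if (length(keep) == 0) {
    stop_invalid("no feature reached average z >= ", threshold,
                 "; review the threshold or the data")
  }
  keep
}
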