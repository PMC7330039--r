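#' Fit a cancer drug-target classification model
#'
#' The central fitting function. Starting from a complete per-gene feature
#' table and a set of known target genes, it:
#' \enumerate{
#'   \item samples ten pairwise disjoint balanced negative (non-target) sets
#'     and builds ten labeled datasets with stratified 70/30 splits;
#'   \item (optionally) screens each feature univariately (Mann-Whitney with
#'     BH correction) on the full data with pooled negatives;
#'   \item in the `extended` regime, selects features whose random-forest
#'     importance exceeds a label-permutation null by an average z-score of
#'     at least `z_threshold`; in the `primary` regime the three primary
#'     features are used directly and selection is skipped;
#'   \item tunes and trains the requested classifier families on each
#'     training split (stratified cross-validated AUROC);
#'   \item evaluates all models on the test splits, picks the best method by
#'     mean AUROC, and retrains it on the full datasets, yielding the final
#'     ensemble of ten models.
#' }
#' `predict()` on the returned object produces the genome-wide ranking.
#'
#' @param features complete feature table from [assemble_feature_table()]
#'   (column `gene` plus numeric feature columns).
#' @param positives character vector of known target genes; genes without
#'   feature data are dropped with a log message.
#' @param regime `"extended"` (primary + embedding features with selection)
#'   or `"primary"` (three primary features, no selection).
#' @param methods classifier families to benchmark (default: all five).
#' @param k_negative number of disjoint negative sets (default 10).
#' @param train_frac training fraction of the stratified split (default 0.7).
#' @param n_shuffles label shuffles for the importance null (default 100).
#' @param z_threshold feature-selection threshold on the average z (default
#'   0.5, inclusive).
#' @param cv_folds cross-validation folds for tuning (default 5).
#' @param grids hyperparameter grids ([default_grids()]).
#' @param univariate run the univariate screen (default TRUE).
#' @param keep_models keep all per-method models in the returned object
#'   (default FALSE; the evaluation table and final ensemble are always
#'   kept).
#' @param seed master seed; every stage derives its own sub-seed from it, so
#'   one integer reproduces the whole ten-replicate design.
#' @return Object of class `target_model`; see [predict.target_model()],
#'   [summary.target_model()], [plot.target_model()].
#' @export
#' @examples
#' \donttest{
#' sc <- simulate_scenario(scenario_config(n_genes = 500, n_targets = 20,
#'                                         mean_degree = 6, seed = 1))
#' emb <- embed_network(sc$network, d = 8, walks_per_node = 3,
#'                      subgraph_size = 15, epochs = 2, seed = 1)
#' feats <- assemble_feature_table(sc$features, emb)
#' fit <- target_model(feats, sc$targets, methods = "logistic_regression",
#'                     n_shuffles = 10, seed = 1)
#' head(predict(fit))
#' }
target_model <- function(features, positives,
                         regime = c("extended", "primary"),
                         methods = tr_methods(),
                         k_negative = 10L, train_frac = 0.7,
                         n_shuffles = 100L, z_threshold = 0.5,
                         cv_folds = 5L, grids = default_grids(),
                         univariate = TRUE, keep_models = FALSE, seed = 1L) {
  regime <- match.arg(regime)
  methods <- match.arg(methods, tr_methods(), several.ok = TRUE)
  cl <- match.call()

  pos_data <- intersect(positives, features$gene)
  if (length(pos_data) < length(positives)) {
    log_note("target_model: %d positive(s) lack complete data and were dropped",
             length(positives) - length(pos_data))
  }
  if (length(pos_data) < 4) stop_invalid("too few positives with data (need >= 4)")

  negatives <- sample_negative_sets(features$gene, pos_data, k = k_negative,
                                    seed = derive_seed(seed, "negatives"))
  primary_feats <- intersect(c("mutation_rate", "expression", "essentiality"),
                             names(features))
  if (regime == "primary") {
    used <- features[, c("gene", primary_feats), drop = FALSE]
  } else {
    used <- features
  }
  datasets <- build_datasets(used, pos_data, negatives,
                             train_frac = train_frac, seed = seed)

  uni <- if (univariate) univariate_screen(used, pos_data, negatives) else NULL

  if (regime == "extended") {
    importance <- feature_importance_report(datasets, n_shuffles = n_shuffles,
                                            seed = seed)
    selected <- select_features(importance, threshold = z_threshold)
  } else {
    importance <- NULL
    selected <- primary_feats
  }

  models <- train_all(datasets, selected, methods = methods, grids = grids,
                      cv_folds = cv_folds, seed = seed)
  evaluation <- evaluate_models(models, datasets)
  ensemble <- retrain_full(datasets, evaluation$best_method, models,
                           features = selected, seed = seed)

  structure(list(call = cl, regime = regime, methods = methods,
                 features = features, positives = pos_data,
                 negatives = negatives, datasets = datasets,
                 univariate = uni, importance = importance,
                 selected_features = selected,
                 models = if (keep_models) models else NULL,
                 evaluation = evaluation, best_method = evaluation$best_method,
                 ensemble = ensemble, seed = as.integer(seed),
                 params = list(k_negative = k_negative, train_frac = train_frac,
                               n_shuffles = n_shuffles, z_threshold = z_threshold,
                               cv_folds = cv_folds)),
            class = "target_model")
}

#' @export
print.target_model <- function(x, ...) {
  cat("Cancer target classification model (", x$regime, " regime)\n", sep = "")
  cat(sprintf("  %d positives, %d x %d negatives, %d feature(s) used\n",
              length(x$positives), x$params$k_negative, length(x$positives),
              length(x$selected_features)))
  cat(sprintf("  best method: %s (mean test AUROC %.3f)\n", x$best_method,
              x$evaluation$mean_auroc[x$best_method]))
  invisible(x)
}

#' Summarize a fitted target model
#'
#' @param object a `target_model`.
#' @param ... unused.
#' @return Object of class `summary.target_model` with the evaluation table,
#'   selected features and (when run) the univariate screen.
#' @export
summary.target_model <- function(object, ...) {
  structure(list(regime = object$regime,
                 n_pos = length(object$positives),
                 evaluation = object$evaluation,
                 selected_features = object$selected_features,
                 avg_z = if (!is.null(object$importance)) object$importance$avg_z,
                 univariate = object$univariate),
            class = "summary.target_model")
}

#' @export
print.summary.target_model <- function(x, ...) {
  cat("Regime:", x$regime, "|", x$n_pos, "positive genes\n\n")
  print(x$evaluation)
  cat("\nSelected features (", length(x$selected_features), "):\n  ",
      paste(x$selected_features, collapse = ", "), "\n", sep = "")
  if (!is.null(x$univariate)) {
    sig <- sum(x$univariate$q < 0.05)
    cat(sprintf("\nUnivariate screen: %d/%d features with q < 0.05\n",
                sig, nrow(x$univariate)))
  }
  invisible(x)
}

#' Genome-wide prediction from a fitted target model
#'
#' Applies the final ensemble to every gene of the feature table (or of
#' `newdata`) except the positives, with the nine-model rule for negative-set
#' members, returning the ranked table.
#'
#' @param object a `target_model`.
#' @param newdata optional feature table; defaults to the table the model was
#'   fitted on.
#' @param ... unused.
#' @return A `prediction_ranking` data.frame; see [predict_genomewide()].
#' @export
predict.target_model <- function(object, newdata = NULL, ...) {
  features <- if (is.null(newdata)) object$features else newdata
  predict_genomewide(object$ensemble, features, object$positives,
                     object$negatives)
}

#' Plot per-method test AUROCs of a fitted target model
#'
#' Box plot of the ten per-negative-set test AUROCs for each benchmarked
#' method, with the random-guess baseline at 0.5.
#'
#' @param x a `target_model`.
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.target_model <- function(x, ...) {
  mat <- t(x$evaluation$auroc)
  boxplot(mat, ylab = "test AUROC", las = 2, ...)
  abline(h = 0.5, lty = 2)
  invisible(x)
}
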