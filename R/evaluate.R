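#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive is scored above a randomly
#' chosen negative, with ties counting one half — computed from ranks, so it
#' equals the exhaustive pairwise count.
#'
#' @param scores numeric classifier scores.
#' @param labels logical (or 0/1, or factor with `target` level) class labels;
#'   both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
auroc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == "target"
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop_invalid("scores and labels must be complete and of equal length")
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop_invalid("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate trained models on their test splits
#'
#' Scores every model of every method on the test split of its negative-set
#' dataset, averages the ten AUROCs per method, and records the
#' best-performing method (argmax of the mean; ties resolve to the first
#' method in the supplied order).
#'
#' @param models nested list from [train_all()].
#' @param datasets the matching list of labeled datasets.
#' @return Object of class `evaluation_report`: list with `auroc` (method x
#'   negative-set matrix), `mean_auroc` (named vector), `best_method`.
#' @export
evaluate_models <- function(models, datasets) {
  methods <- names(models)
  mat <- matrix(NA_real_, length(methods), length(datasets),
                dimnames = list(methods, NULL))
  for (m in methods) {
    for (i in seq_along(datasets)) {
      test <- datasets[[i]][datasets[[i]]$split == "test", , drop = FALSE]
      mat[m, i] <- auroc(predict_prob(models[[m]][[i]], test),
                         test$label == "target")
    }
  }
  means <- rowMeans(mat)
  structure(list(auroc = mat, mean_auroc = means,
                 best_method = methods[which.max(means)]),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Model evaluation (test-set AUROC, mean over",
      ncol(x$auroc), "negative sets)\n")
  tab <- cbind(mean = round(x$mean_auroc, 3),
               min = round(apply(x$auroc, 1, min), 3),
               max = round(apply(x$auroc, 1, max), 3))
  print(tab)
  cat("Best method:", x$best_method, "\n")
  invisible(x)
}

#' Retrain the chosen method on the full datasets
#'
#' Refits the best method on the complete rows (training + test) of each
#' negative-set dataset, keeping the hyperparameters tuned on the training
#' split, which yields an ensemble of related models differing only in the
#' negative rows they saw.
#'
#' @param datasets list of labeled datasets.
#' @param best_method the method to retrain.
#' @param models the [train_all()] output (source of tuned parameters).
#' @param features feature columns used for training.
#' @param seed master seed.
#' @return Object of class `tr_ensemble`: list with `method`, `models` (one
#'   `tr_model` per negative set), `features`.
#' @export
retrain_full <- function(datasets, best_method, models, features, seed = 1L) {
  fits <- lapply(seq_along(datasets), function(i) {
    params <- models[[best_method]][[i]]$params
    params <- if (length(params)) as.data.frame(params) else NULL
    fit_model(datasets[[i]], best_method, params = params, features = features,
              seed = derive_seed(seed, "retrain", i))
  })
  structure(list(method = best_method, models = fits, features = features),
            class = "tr_ensemble")
}

#' Genome-wide ensemble prediction and ranking
#'
#' Predicts a target probability for every gene in the feature table except
#' the positives, averaging over the ensemble members. For a gene belonging
#' to negative set *i*, model *i* saw that gene labeled as a non-target, so
#' only the other nine models contribute to its average. Genes are ranked by
#' decreasing mean probability (ties broken by gene symbol) and the mean
#' probabilities are additionally expressed as z-scores over the ranked
#' genes so rankings from different cancer types are comparable.
#'
#' @param ensemble a `tr_ensemble` from [retrain_full()].
#' @param features complete feature table covering the prediction universe.
#' @param positives positive genes (excluded from the output).
#' @param negatives the `negative_sets` collection used in training.
#' @return data.frame (class `prediction_ranking`) with columns `gene`,
#'   `mean_probability`, `n_models`, `zscore`, `rank`, sorted by rank; the
#'   fraction of genes above probability 0.5 is attached as attribute
#'   `frac_above_half` (a calibration diagnostic only — the ranking is the
#'   result).
#' @export
predict_genomewide <- function(ensemble, features, positives, negatives) {
  stopifnot(inherits(ensemble, "tr_ensemble"))
  keep <- !(features$gene %in% positives)
  tab <- features[keep, , drop = FALSE]
  if (nrow(tab) == 0) stop_invalid("no genes left to predict")
  k <- length(ensemble$models)
  prob <- matrix(NA_real_, nrow(tab), k)
  for (i in seq_len(k)) {
    prob[, i] <- predict_prob(ensemble$models[[i]], tab)
  }
  for (i in seq_along(negatives)) {
    if (i <= k) prob[tab$gene %in% negatives[[i]], i] <- NA
  }
  n_models <- rowSums(!is.na(prob))
  if (any(n_models == 0)) {
    stop_invalid("gene(s) with no contributing model; negative sets exceed ensemble")
  }
  mean_prob <- rowMeans(prob, na.rm = TRUE)
  z <- as.vector(scale(mean_prob))
  ord <- order(-mean_prob, tab$gene)
  out <- data.frame(gene = tab$gene, mean_probability = mean_prob,
                    n_models = as.integer(n_models), zscore = z,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "frac_above_half") <- mean(mean_prob > 0.5)
  class(out) <- c("prediction_ranking", "data.frame")
  out
}

#' Spearman validation of a ranking against citation counts
#'
#' Samples `n_sample` ranked genes and correlates their predicted target
#' probabilities with per-gene citation counts (Spearman). Genes absent from
#' the citation table are treated as having zero citations (their number is
#' logged), mirroring literature-coverage gaps.
#'
#' @param ranking a `prediction_ranking`.
#' @param citation_counts named numeric vector, or data.frame with columns
#'   `gene` and `citations`.
#' @param n_sample genes to sample (default 1000; capped at the ranking size
#'   with a warning).
#' @param seed integer seed for the sample.
#' @return List with `rho`, `p` and `n` (genes used).
#' @export
citation_validation <- function(ranking, citation_counts, n_sample = 1000L,
                                seed = 1L) {
  if (is.data.frame(citation_counts)) {
    cc <- citation_counts$citations
    names(cc) <- citation_counts$gene
    citation_counts <- cc
  }
  if (n_sample > nrow(ranking)) {
    warning("n_sample exceeds ranked genes; using all ", nrow(ranking))
    n_sample <- nrow(ranking)
  }
  picked <- with_seed(derive_seed(seed, "citation"),
                      ranking[sample(nrow(ranking), n_sample), , drop = FALSE])
  cites <- citation_counts[picked$gene]
  n_missing <- sum(is.na(cites))
  if (n_missing > 0) {
    log_note("citation_validation: %d gene(s) missing from citation table, treated as 0",
             n_missing)
    cites[is.na(cites)] <- 0
  }
  ct <- suppressWarnings(cor.test(picked$mean_probability, as.numeric(cites),
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n_sample)
}
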