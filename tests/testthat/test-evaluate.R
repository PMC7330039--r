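test_that("auroc equals the exhaustive pairwise oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.3, 0.6, 0.2), c(1, 0, 0, 1)), 0.5)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(11)
  for (i in 1:300) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("evaluation averages test AUROCs and names the best method", {
  ds <- tiny_datasets()
  grids <- default_grids()
  grids$random_forest <- grids$random_forest[2, , drop = FALSE]
  models <- train_all(ds, features = c("mutation_rate", "expression",
                                       "essentiality"),
                      methods = c("random_forest", "logistic_regression"),
                      grids = grids, seed = 6)
  ev <- evaluate_models(models, ds)
  expect_equal(dim(ev$auroc), c(2, 10))
  expect_true(all(ev$auroc >= 0 & ev$auroc <= 1))
  expect_equal(unname(ev$mean_auroc), unname(rowMeans(ev$auroc)))
  expect_equal(ev$best_method,
               names(which.max(ev$mean_auroc)))
  # planted signal: both methods clearly beat chance on test data
  expect_gt(min(ev$mean_auroc), 0.7)
  .tr_cache$eval_models <- models
  .tr_cache$eval_report <- ev
})

test_that("retraining builds a ten-model ensemble on the full datasets", {
  ds <- tiny_datasets()
  models <- .tr_cache$eval_models
  ens <- retrain_full(ds, "logistic_regression", models,
                      features = c("mutation_rate", "expression",
                                   "essentiality"), seed = 6)
  expect_s3_class(ens, "tr_ensemble")
  expect_length(ens$models, 10)
  # trained on the full balanced data: train + test rows
  expect_equal(length(ens$models[[1]]$fit$fitted.values), nrow(ds[[1]]))
  expect_equal(nrow(ds[[1]]), 2 * sum(ds[[1]]$label == "target"))
})

test_that("genome-wide prediction excludes positives and applies the 9-model rule", {
  sc <- tiny_scenario()
  ds <- tiny_datasets()
  negs <- tiny_negatives()
  ens <- retrain_full(ds, "logistic_regression", .tr_cache$eval_models,
                      features = c("mutation_rate", "expression",
                                   "essentiality"), seed = 6)
  rk <- predict_genomewide(ens, sc$feature_table, sc$targets, negs)
  expect_s3_class(rk, "prediction_ranking")
  expect_length(intersect(rk$gene, sc$targets), 0)
  expect_equal(nrow(rk), nrow(sc$feature_table) - length(sc$targets))
  in_neg <- rk$gene %in% unlist(negs)
  expect_true(all(rk$n_models[in_neg] == 9))
  expect_true(all(rk$n_models[!in_neg] == 10))
  expect_equal(mean(rk$zscore), 0, tolerance = 1e-9)
  expect_equal(sd(rk$zscore), 1, tolerance = 1e-9)
  expect_equal(sort(rk$rank), seq_len(nrow(rk)))
  expect_true(all(diff(rk$mean_probability) <= 1e-12))
  # deterministic tie rule: equal probabilities ranked by gene symbol
  ties <- rk[duplicated(rk$mean_probability) |
               duplicated(rk$mean_probability, fromLast = TRUE), ]
  if (nrow(ties) > 1) {
    for (p in unique(ties$mean_probability)) {
      expect_false(is.unsorted(ties$gene[ties$mean_probability == p]))
    }
  }
})

test_that("citation validation matches the rank-correlation oracle", {
  rk <- data.frame(gene = sprintf("G%02d", 1:30),
                   mean_probability = seq(0.9, 0.1, length.out = 30))
  class(rk) <- c("prediction_ranking", "data.frame")
  counts <- rank(rk$mean_probability)
  names(counts) <- rk$gene
  v <- citation_validation(rk, counts, n_sample = 30, seed = 1)
  expect_equal(v$rho, 1.0, tolerance = 1e-12)
  v2 <- citation_validation(rk, max(counts) + 1 - counts, n_sample = 30, seed = 1)
  expect_equal(v2$rho, -1.0, tolerance = 1e-12)

  set.seed(4)
  x <- c(0.3, 0.9, 0.1, 0.5, 0.7, 0.2)
  y <- c(2, 11, 5, 7, 3, 2)
  rk6 <- data.frame(gene = letters[1:6], mean_probability = x)
  class(rk6) <- c("prediction_ranking", "data.frame")
  cc <- y; names(cc) <- letters[1:6]
  v3 <- citation_validation(rk6, cc, n_sample = 6, seed = 2)
  expect_equal(v3$rho, oracle_spearman(x, y), tolerance = 1e-12)

  expect_warning(citation_validation(rk6, cc, n_sample = 10, seed = 1),
                 "using all")
  cc2 <- cc[1:3]
  expect_message(citation_validation(rk6, cc2, n_sample = 6, seed = 1),
                 "treated as 0")
})
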