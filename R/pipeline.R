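#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()], with the standard defaults of the
#' analysis: ten negative sets, 70/30 stratified split, 100-shuffle
#' importance null with z-threshold 0.5, 32-dimensional embedding, 5-fold
#' tuning.
#'
#' @param input_dir directory of input files (as written by
#'   [write_scenario()] / [make_fixtures()]): `features_primary.tsv`,
#'   `network_edges.tsv`, `targets.txt`. NULL to simulate from `scenario`.
#' @param scenario a [scenario_config()] used when `input_dir` is NULL.
#' @param cancer_label label for reports.
#' @param regime `"extended"` or `"primary"`.
#' @param methods classifier families to benchmark.
#' @param d embedding dimension.
#' @param walks_per_node,subgraph_size,window,epochs embedding parameters.
#' @param k_negative,train_frac,n_shuffles,z_threshold,cv_folds modeling
#'   parameters (see [target_model()]).
#' @param seed master seed.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, scenario = scenario_config(),
                            cancer_label = "synthetic",
                            regime = "extended", methods = tr_methods(),
                            d = 32L, walks_per_node = 10L, subgraph_size = 40L,
                            window = 5L, epochs = 5L,
                            k_negative = 10L, train_frac = 0.7,
                            n_shuffles = 100L, z_threshold = 0.5,
                            cv_folds = 5L, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full target-prediction pipeline
#'
#' Executes the workflow end to end — inputs (file-based or simulated),
#' network embedding, dataset assembly, univariate screen, feature selection,
#' model benchmarking, best-method retraining, genome-wide ranking — and
#' writes every intermediate report plus a manifest into `output_dir`.
#' Re-running with the same config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param output_dir run directory (created); NULL to skip writing files.
#' @return Invisibly, a list with the fitted `target_model`, the `ranking`,
#'   the embedding, and `output_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$input_dir)) {
    need <- file.path(config$input_dir,
                      c("features_primary.tsv", "network_edges.tsv", "targets.txt"))
    for (f in need) if (!file.exists(f)) stop_invalid("missing input file: ", f)
    primary <- read_tsv_file(need[1])
    names(primary)[1] <- "gene"
    positives <- readLines(need[3])
    network <- load_edge_list(need[2], universe = primary$gene)
  } else {
    sc <- simulate_scenario(config$scenario, cancer_label = config$cancer_label)
    primary <- sc$features
    positives <- sc$targets
    network <- sc$network
  }

  embedding <- embed_network(network, d = config$d,
                             walks_per_node = config$walks_per_node,
                             subgraph_size = config$subgraph_size,
                             window = config$window, epochs = config$epochs,
                             seed = config$seed)
  features <- assemble_feature_table(primary, embedding)
  fit <- target_model(features, positives, regime = config$regime,
                      methods = config$methods, k_negative = config$k_negative,
                      train_frac = config$train_frac,
                      n_shuffles = config$n_shuffles,
                      z_threshold = config$z_threshold,
                      cv_folds = config$cv_folds, seed = config$seed)
  ranking <- predict(fit)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_embedding(embedding, file.path(output_dir, "embedding.tsv"))
    if (!is.null(fit$univariate)) {
      write_tsv_file(fit$univariate, file.path(output_dir, "univariate.tsv"))
    }
    if (!is.null(fit$importance)) {
      imp <- data.frame(feature = names(fit$importance$avg_z),
                        avg_z = unname(fit$importance$avg_z),
                        selected = names(fit$importance$avg_z) %in%
                          fit$selected_features)
      write_tsv_file(imp, file.path(output_dir, "importance.tsv"))
    }
    ev <- data.frame(method = rownames(fit$evaluation$auroc),
                     fit$evaluation$auroc, check.names = FALSE,
                     mean_auroc = fit$evaluation$mean_auroc)
    colnames(ev) <- c("method", sprintf("auroc_set_%d",
                                        seq_len(ncol(fit$evaluation$auroc))),
                      "mean_auroc")
    write_tsv_file(ev, file.path(output_dir, "evaluation.tsv"))
    write_tsv_file(as.data.frame(ranking), file.path(output_dir, "ranking.tsv"))
    manifest <- c(sprintf("package_version=%s",
                          as.character(utils::packageVersion("targetrank"))),
                  sprintf("cancer_label=%s", config$cancer_label),
                  sprintf("regime=%s", config$regime),
                  sprintf("best_method=%s", fit$best_method),
                  sprintf("seed=%d", config$seed),
                  sprintf("d=%d", config$d),
                  sprintf("k_negative=%d", config$k_negative),
                  sprintf("n_shuffles=%d", config$n_shuffles),
                  sprintf("z_threshold=%g", config$z_threshold),
                  sprintf("train_frac=%g", config$train_frac),
                  sprintf("cv_folds=%d", config$cv_folds))
    writeLines(manifest, file.path(output_dir, "manifest.txt"))
  }
  invisible(list(fit = fit, ranking = ranking, embedding = embedding,
                 output_dir = output_dir))
}

#' Named fixture scenarios
#'
#' Three documented study conditions used throughout the package's
#' validation:
#' \describe{
#'   \item{null}{no planted signal anywhere: all effect sizes 0 and targets
#'     wired randomly. Any downstream discrimination is spurious, so test
#'     AUROCs should calibrate to 0.5. Uses a larger positive class (100)
#'     so per-set AUROC averages are stable.}
#'   \item{signal}{informative mutation (+2 SD) and expression (+1.5 SD),
#'     uninformative essentiality, targets wired into dense communities.}
#'   \item{community}{signal carried almost entirely by the network: weak
#'     mutation shift (+0.5 SD), no expression/essentiality shift, strong
#'     community wiring — the condition under which embedding features must
#'     add value over the primary ones.}
#' }
#'
#' @param name one of `"null"`, `"signal"`, `"community"`.
#' @param seed master seed.
#' @return A [scenario_config()].
#' @export
fixture_scenario <- function(name, seed = 1L) {
  switch(name,
    null = scenario_config(n_genes = 2400L, n_targets = 100L,
                           effect_sizes = c(mutation = 0, expression = 0,
                                            essentiality = 0),
                           target_affinity = 0, seed = seed),
    signal = scenario_config(n_genes = 2000L, n_targets = 80L,
                             effect_sizes = c(mutation = 2, expression = 1.5,
                                              essentiality = 0),
                             target_affinity = 0.9, seed = seed),
    community = scenario_config(n_genes = 2000L, n_targets = 80L,
                                effect_sizes = c(mutation = 0.5, expression = 0,
                                                 essentiality = 0),
                                target_affinity = 0.95, seed = seed),
    stop_invalid("unknown scenario '", name,
                 "'; valid names: null, signal, community"))
}

#' Write a named fixture bundle to disk
#'
#' Simulates one of the named scenarios ([fixture_scenario()]) and writes the
#' complete miniature input bundle (feature table, sample matrices, edge
#' list, target list, config). For the `signal` and `community` scenarios, 20
#' planted targets are withheld from the written positive list (and saved to
#' `heldout_targets.txt`) so held-out recovery can be assessed.
#'
#' @param name scenario name.
#' @param seed master seed; the bundle is byte-identical for a given
#'   name and seed.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(name, seed = 1L, dir = tempfile("fixtures_")) {
  cfg <- fixture_scenario(name, seed = seed)
  sc <- simulate_scenario(cfg, cancer_label = name)
  holdout <- NULL
  if (name %in% c("signal", "community")) {
    holdout <- with_seed(derive_seed(seed, "misc"), sort(sample(sc$targets, 20)))
  }
  write_scenario(sc, dir, holdout_targets = holdout)
  invisible(dir)
}

#' Assemble in-memory inputs for a named fixture scenario
#'
#' Simulates the named scenario, embeds its interaction network, joins the
#' full 35-column feature table, and (for the `signal` and `community`
#' scenarios) withholds 20 planted targets from the positive set so that
#' recovery of never-labeled targets can be measured. This is the in-memory
#' counterpart of [make_fixtures()].
#'
#' @param name scenario name (see [fixture_scenario()]).
#' @param seed master seed.
#' @param d embedding dimension (default 32).
#' @return List with `features` (complete feature table), `positives`,
#'   `holdout` (withheld planted targets, possibly empty), `scenario`,
#'   `embedding` and `config`.
#' @export
fixture_inputs <- function(name, seed = 1L, d = 32L) {
  cfg <- fixture_scenario(name, seed = seed)
  sc <- simulate_scenario(cfg, cancer_label = name)
  emb <- embed_network(sc$network, d = d, seed = seed)
  features <- assemble_feature_table(sc$features, emb)
  holdout <- character(0)
  if (name %in% c("signal", "community")) {
    holdout <- with_seed(derive_seed(seed, "misc"), sort(sample(sc$targets, 20)))
  }
  positives <- setdiff(sc$targets, holdout)
  list(name = name, features = features, positives = positives,
       holdout = holdout, scenario = sc, embedding = emb, config = cfg)
}
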