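# Shared small scenario, built lazily and memoized so several test files can
# reuse it without regenerating.

.tr_cache <- new.env(parent = emptyenv())

tiny_scenario <- function() {
  if (is.null(.tr_cache$tiny)) {
    cfg <- scenario_config(n_genes = 500L, n_targets = 20L, mean_degree = 6,
                           n_samples = c(mutation = 60L, expression = 60L,
                                         essentiality = 20L),
                           seed = 42L)
    sc <- simulate_scenario(cfg)
    emb <- suppressMessages(
      embed_network(sc$network, d = 8, walks_per_node = 5, subgraph_size = 15,
                    epochs = 3, seed = 42))
    sc$embedding <- emb
    sc$feature_table <- suppressMessages(assemble_feature_table(sc$features, emb))
    .tr_cache$tiny <- sc
  }
  .tr_cache$tiny
}

tiny_datasets <- function() {
  if (is.null(.tr_cache$tiny_ds)) {
    sc <- tiny_scenario()
    negs <- sample_negative_sets(sc$feature_table$gene, sc$targets, seed = 7)
    .tr_cache$tiny_negs <- negs
    .tr_cache$tiny_ds <- build_datasets(sc$feature_table, sc$targets, negs,
                                        seed = 7)
  }
  .tr_cache$tiny_ds
}

tiny_negatives <- function() {
  tiny_datasets()
  .tr_cache$tiny_negs
}

# balanced toy dataset built directly: feature f1 carries the label signal,
# the rest are noise
toy_dataset <- function(n_per_class = 30, n_noise = 5, signal = 2, seed = 1,
                        split = TRUE) {
  set.seed(seed)
  n <- 2 * n_per_class
  label <- factor(rep(c("non_target", "target"), each = n_per_class),
                  levels = c("non_target", "target"))
  x <- matrix(rnorm(n * (n_noise + 1)), n,
              dimnames = list(NULL, c("f1", paste0("noise", seq_len(n_noise)))))
  x[, "f1"] <- x[, "f1"] + signal * (label == "target")
  d <- data.frame(gene = sprintf("T%03d", seq_len(n)), label = label, x)
  if (split) d <- stratified_split(d, seed = seed)
  d
}
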