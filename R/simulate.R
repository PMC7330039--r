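#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic benchmark: how many genes and planted
#' targets, per-data-type sample counts, target-versus-background effect sizes
#' for the three primary features, and the interaction-network layout.
#'
#' Effect sizes are standardized mean shifts: the planted targets' gene-level
#' feature mean is moved by `effect * SD(background gene-level distribution)`.
#' An effect of 0 makes the feature uninformative. Network signal is planted
#' through community membership: with probability `target_affinity` a target
#' gene is assigned to one of `n_informative_communities` designated dense
#' communities, so class signal is carried by the network neighborhood rather
#' than by node degree.
#'
#' @param n_genes number of genes in the universe (default 2000).
#' @param n_targets number of planted target genes.
#' @param n_samples named vector of sample counts for mutation, expression and
#'   essentiality matrices.
#' @param effect_sizes named vector of standardized shifts for the three
#'   primary features (default: informative mutation and expression,
#'   uninformative essentiality).
#' @param mean_degree expected average node degree of the interaction network.
#' @param n_communities number of network communities.
#' @param n_informative_communities communities into which targets are
#'   preferentially wired.
#' @param target_affinity probability that a target is placed in an
#'   informative community (0 = random wiring, no network signal).
#' @param community_mix within-community edge affinity multiplier.
#' @param informative_density extra density multiplier for informative
#'   communities.
#' @param seed master seed; all generator randomness derives from it.
#' @return An object of class `scenario_config` (a named list).
#' @export
#' @examples
#' cfg <- scenario_config(n_genes = 200, n_targets = 10, seed = 1)
#' cfg$effect_sizes
scenario_config <- function(n_genes = 2000L,
                            n_targets = 80L,
                            n_samples = c(mutation = 150L, expression = 150L,
                                          essentiality = 25L),
                            effect_sizes = c(mutation = 2, expression = 1.5,
                                             essentiality = 0),
                            mean_degree = 8,
                            n_communities = 8L,
                            n_informative_communities = 2L,
                            target_affinity = 0.9,
                            community_mix = 8,
                            informative_density = 2,
                            seed = 1L) {
  stopifnot(n_genes > 0, n_targets > 0, all(n_samples > 0),
            n_communities >= 1, n_informative_communities >= 1,
            n_informative_communities <= n_communities,
            target_affinity >= 0, target_affinity <= 1)
  need <- c("mutation", "expression", "essentiality")
  if (!all(need %in% names(n_samples)) || !all(need %in% names(effect_sizes))) {
    stop_invalid("n_samples and effect_sizes must be named for: ",
                 paste(need, collapse = ", "))
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_targets = as.integer(n_targets),
                 n_samples = n_samples[need],
                 effect_sizes = effect_sizes[need],
                 mean_degree = mean_degree,
                 n_communities = as.integer(n_communities),
                 n_informative_communities = as.integer(n_informative_communities),
                 target_affinity = target_affinity,
                 community_mix = community_mix,
                 informative_density = informative_density,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate a gene universe
#'
#' Creates `n_genes` unique gene symbols. The symbol scheme is index-based
#' (`G00001`, `G00002`, ...), so the same `n_genes` always yields the same
#' symbols regardless of `seed`; the seed is accepted for interface symmetry
#' with the other generators and recorded as an attribute.
#'
#' @param n_genes number of genes, at least 50.
#' @param seed integer seed (recorded; symbols are index-based).
#' @return Character vector of unique gene symbols.
#' @export
#' @examples
#' head(generate_universe(100, seed = 1))
generate_universe <- function(n_genes, seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 50) {
    stop_invalid("n_genes must be a single number >= 50")
  }
  genes <- sprintf("G%05d", seq_len(n_genes))
  attr(genes, "seed") <- as.integer(seed)
  genes
}

#' Generate a modular, degree-heterogeneous interaction network
#'
#' Samples an undirected gene-gene network from a degree-corrected block
#' model: node propensities follow a heavy-tailed (Pareto) law, edges within a
#' community are `community_mix` times more likely than between communities,
#' and the designated informative communities carry an extra density factor.
#' Target genes (if supplied) are preferentially assigned to the informative
#' communities with probability `target_affinity`, which plants class signal
#' in the network neighborhood without relying on degree.
#'
#' Edge probabilities are rescaled so that the expected mean degree matches
#' `config$mean_degree`; `mean_degree = 0` yields an empty edge set.
#'
#' @param universe character vector of gene symbols (from
#'   [generate_universe()]).
#' @param config a [scenario_config()].
#' @param targets optional character vector of planted target genes.
#' @return An undirected [igraph][igraph::graph] object with one vertex per
#'   gene (isolated vertices allowed), vertex attribute `community`, and graph
#'   attribute `informative_communities`.
#' @export
generate_network <- function(universe, config, targets = NULL) {
  n <- length(universe)
  if (n != config$n_genes) {
    stop_invalid("universe size (", n, ") does not match config$n_genes (",
                 config$n_genes, ")")
  }
  if (!is.null(targets) && !all(targets %in% universe)) {
    stop_invalid("targets must be a subset of the universe")
  }
  seed <- derive_seed(config$seed, "network")
  with_seed(seed, {
    k <- config$n_communities
    inf <- seq_len(config$n_informative_communities)
    comm <- sample.int(k, n, replace = TRUE)
    names(comm) <- universe
    if (!is.null(targets) && config$target_affinity > 0) {
      idx <- match(targets, universe)
      go_inf <- runif(length(idx)) < config$target_affinity
      comm[idx[go_inf]] <- sample(inf, sum(go_inf), replace = TRUE)
    }

    if (config$mean_degree <= 0) {
      g <- igraph::make_empty_graph(n, directed = FALSE)
      igraph::V(g)$name <- universe
    } else {
      # heavy-tailed expected-degree propensities
      w <- (1 - runif(n))^(-1 / 2.5)
      w <- w / mean(w)
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      i <- pairs[, 1]; j <- pairs[, 2]
      aff <- ifelse(comm[i] == comm[j],
                    config$community_mix *
                      ifelse(comm[i] %in% inf, config$informative_density, 1),
                    1)
      p <- w[i] * w[j] * aff
      target_edges <- n * config$mean_degree / 2
      # calibrate so expected edge count matches despite the 0.95 cap
      for (it in 1:3) {
        p_c <- pmin(p, 0.95)
        p <- p * target_edges / sum(p_c)
      }
      p <- pmin(p, 0.95)
      keep <- runif(length(p)) < p
      g <- igraph::make_empty_graph(n, directed = FALSE)
      igraph::V(g)$name <- universe
      if (any(keep)) {
        g <- igraph::add_edges(g, rbind(i[keep], j[keep]))
        g <- igraph::simplify(g)
      }
    }
    igraph::V(g)$community <- unname(comm[igraph::V(g)$name])
    g <- igraph::set_graph_attr(g, "informative_communities", inf)
    g
  })
}

#' Generate sample-level omics matrices with planted target signal
#'
#' Draws genes-by-samples matrices for the three primary data types. Mutation:
#' each gene has a Bernoulli rate drawn from a right-skewed Beta background
#' (mode near 0.02, mimicking somatic mutation sparsity), shifted upward for
#' targets by `effect * SD(background)` and clipped to \[0, 1\] (with a
#' warning when clipping occurs). Expression: gene-level means on a log-like
#' continuous scale (location-scale normal), shifted for targets. Essentiality:
#' gene-level scores centered near 0 with a negative tail (a CERES-like
#' minority of strongly essential genes); the default target shift is 0,
#' making the feature uninformative.
#'
#' @param universe gene symbols.
#' @param targets character vector of planted targets (subset of universe).
#' @param config a [scenario_config()].
#' @return Named list of three matrices (`mutation`, `expression`,
#'   `essentiality`), each with genes in rows (rownames) and a `data_type`
#'   attribute; mutation entries are in \{0, 1\}.
#' @export
generate_sample_matrices <- function(universe, targets, config) {
  if (!all(targets %in% universe)) {
    stop_invalid("targets must be a subset of the universe")
  }
  n <- length(universe)
  is_tgt <- universe %in% targets
  eff <- config$effect_sizes
  ns <- config$n_samples
  seed <- derive_seed(config$seed, "samples")
  with_seed(seed, {
    ## mutation: Beta(1.5, 25) background -> mode ~0.02, SD ~0.044
    a <- 1.5; b <- 25
    sd_bg <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
    rate <- rbeta(n, a, b)
    rate[is_tgt] <- rate[is_tgt] + eff[["mutation"]] * sd_bg
    if (any(rate < 0 | rate > 1)) {
      warning("mutation rates clipped to [0, 1] after applying effect size")
      rate <- pmin(pmax(rate, 0), 1)
    }
    mut <- matrix(rbinom(n * ns[["mutation"]], 1, rep(rate, ns[["mutation"]])),
                  nrow = n)

    ## expression: gene-level mean N(5, 2) on a log-like scale, sample noise SD 1
    expr_mu <- rnorm(n, 5, 2)
    expr_mu[is_tgt] <- expr_mu[is_tgt] + eff[["expression"]] * 2
    expr <- matrix(rnorm(n * ns[["expression"]], rep(expr_mu, ns[["expression"]]), 1),
                   nrow = n)

    ## essentiality: mostly near 0, 10% strongly essential (negative tail)
    ess_mu <- rnorm(n, -0.1, 0.25)
    essential <- runif(n) < 0.1
    ess_mu[essential] <- rnorm(sum(essential), -1, 0.3)
    sd_ess <- sd(ess_mu)
    ess_mu[is_tgt] <- ess_mu[is_tgt] + eff[["essentiality"]] * sd_ess
    ess <- matrix(rnorm(n * ns[["essentiality"]], rep(ess_mu, ns[["essentiality"]]), 0.15),
                  nrow = n)

    out <- list(mutation = mut, expression = expr, essentiality = ess)
    for (nm in names(out)) {
      rownames(out[[nm]]) <- universe
      attr(out[[nm]], "data_type") <- nm
    }
    out
  })
}

#' Aggregate a sample-level matrix to one value per gene
#'
#' Applies the per-cancer-type aggregation rule for each data type: mutation
#' matrices (binary calls) are averaged per gene, giving a mutation rate in
#' \[0, 1\]; expression and essentiality matrices are summarized by the
#' per-gene median across samples.
#'
#' @param m a genes-by-samples matrix carrying a `data_type` attribute
#'   (`"mutation"`, `"expression"` or `"essentiality"`), as produced by
#'   [generate_sample_matrices()] or built manually.
#' @param data_type override for the `data_type` attribute.
#' @return Named numeric vector, one value per gene.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 0, 1), nrow = 1, dimnames = list("G1", NULL))
#' attr(m, "data_type") <- "mutation"
#' aggregate_samples(m)  # 0.5
aggregate_samples <- function(m, data_type = attr(m, "data_type")) {
  if (is.null(data_type) ||
      !data_type %in% c("mutation", "expression", "essentiality")) {
    stop_invalid("data_type must be one of mutation/expression/essentiality")
  }
  if (!is.matrix(m) || ncol(m) < 1L) {
    stop_invalid("matrix must have at least one sample column")
  }
  if (data_type == "mutation") {
    if (!all(m %in% c(0, 1))) stop_invalid("mutation matrix entries must be 0/1")
    v <- rowMeans(m)
  } else {
    v <- apply(m, 1, median)
  }
  names(v) <- rownames(m)
  v
}

#' Simulate a complete synthetic scenario
#'
#' Runs the full generator: universe, planted target set, interaction network
#' with community-wired targets, sample-level matrices, and the aggregated
#' primary feature table. Fully deterministic for a given config (including
#' its seed).
#'
#' @param config a [scenario_config()].
#' @param cancer_label label recorded with the target set.
#' @return A list with elements `universe`, `targets` (character vector with
#'   `cancer_label` attribute), `network`, `matrices`, and `features` (a
#'   data.frame: gene, mutation_rate, expression, essentiality).
#' @export
#' @examples
#' sc <- simulate_scenario(scenario_config(n_genes = 200, n_targets = 8,
#'                                         mean_degree = 4, seed = 1))
#' str(sc$features)
simulate_scenario <- function(config, cancer_label = "synthetic") {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n_genes < 2 * config$n_targets * 11) {
    stop_invalid("universe too small: need n_genes >= ", 2 * config$n_targets * 11,
                 " for ", config$n_targets, " targets plus ten disjoint negative sets")
  }
  universe <- generate_universe(config$n_genes, config$seed)
  targets <- with_seed(derive_seed(config$seed, "targets"),
                       sort(sample(universe, config$n_targets)))
  attr(targets, "cancer_label") <- cancer_label
  network <- generate_network(universe, config, targets = targets)
  matrices <- generate_sample_matrices(universe, targets, config)
  features <- data.frame(
    gene = universe,
    mutation_rate = unname(aggregate_samples(matrices$mutation)),
    expression = unname(aggregate_samples(matrices$expression)),
    essentiality = unname(aggregate_samples(matrices$essentiality)),
    stringsAsFactors = FALSE)
  list(universe = universe, targets = targets, network = network,
       matrices = matrices, features = features, config = config)
}
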