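test_that("gene universe generation is deterministic, unique and guarded", {
  u1 <- generate_universe(100, seed = 1)
  u2 <- generate_universe(100, seed = 1)
  expect_identical(as.character(u1), as.character(u2))
  expect_equal(length(u1), 100)
  expect_equal(anyDuplicated(u1), 0)
  # index-based symbol scheme: identical across seeds by design
  expect_identical(as.character(generate_universe(100, seed = 2)),
                   as.character(u1))
  expect_error(generate_universe(10, seed = 1), "50")
})

test_that("network generation matches the expected edge count and is simple", {
  cfg <- scenario_config(n_genes = 100L, n_targets = 5L, mean_degree = 6,
                         seed = 3)
  u <- generate_universe(100)
  for (s in 1:3) {
    cfg$seed <- s
    g <- generate_network(u, cfg)
    expect_true(igraph::is_simple(g))
    expect_equal(igraph::vcount(g), 100)
    # expected edges = n * mean_degree / 2 = 300; allow 20%
    expect_gt(igraph::ecount(g), 240)
    expect_lt(igraph::ecount(g), 360)
  }
  expect_error(generate_network(generate_universe(50), cfg), "does not match")
})

test_that("planted communities beat a random partition in modularity", {
  cfg <- scenario_config(n_genes = 300L, n_targets = 10L, mean_degree = 8,
                         n_communities = 2L, n_informative_communities = 1L,
                         community_mix = 10, seed = 5)
  g <- generate_network(generate_universe(300), cfg)
  planted <- igraph::V(g)$community
  m_planted <- igraph::modularity(g, planted)
  m_random <- igraph::modularity(g, with_seed(1, sample(planted)))
  expect_gt(m_planted, m_random)
  expect_gt(m_planted, 0.2)
})

test_that("zero mean degree yields an edgeless network", {
  cfg <- scenario_config(n_genes = 60L, n_targets = 2L, mean_degree = 0, seed = 1)
  g <- generate_network(generate_universe(60), cfg)
  expect_equal(igraph::ecount(g), 0)
  expect_equal(igraph::vcount(g), 60)
})

test_that("targets are preferentially wired into informative communities", {
  cfg <- scenario_config(n_genes = 400L, n_targets = 40L, mean_degree = 6,
                         n_communities = 8L, n_informative_communities = 2L,
                         target_affinity = 0.9, seed = 9)
  u <- generate_universe(400)
  tgt <- u[1:40]
  g <- generate_network(u, cfg, targets = tgt)
  comm <- igraph::V(g)$community
  inf <- igraph::graph_attr(g, "informative_communities")
  frac_tgt <- mean(comm[match(tgt, igraph::V(g)$name)] %in% inf)
  frac_bg <- mean(comm[!(igraph::V(g)$name %in% tgt)] %in% inf)
  expect_gt(frac_tgt, 0.7)
  expect_lt(frac_bg, 0.5)
})

test_that("sample matrices have the right shape and planted mutation signal", {
  cfg <- scenario_config(n_genes = 700L, n_targets = 30L,
                         n_samples = c(mutation = 50L, expression = 10L,
                                       essentiality = 10L),
                         effect_sizes = c(mutation = 3, expression = 0,
                                          essentiality = 0),
                         seed = 11)
  u <- generate_universe(700)
  tgt <- u[1:30]
  mats <- generate_sample_matrices(u, tgt, cfg)
  expect_named(mats, c("mutation", "expression", "essentiality"))
  for (m in mats) expect_equal(nrow(m), 700)
  expect_equal(ncol(mats$mutation), 50)
  expect_true(all(mats$mutation %in% c(0, 1)))
  # +3 SD mutation shift detectable on aggregated rates
  rate <- aggregate_samples(mats$mutation)
  p <- wilcox.test(rate[tgt], rate[setdiff(u, tgt)],
                   alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("a zero essentiality effect leaves target and background alike", {
  pvals <- vapply(1:20, function(s) {
    cfg <- scenario_config(n_genes = 250L, n_targets = 25L,
                           n_samples = c(mutation = 2L, expression = 2L,
                                         essentiality = 10L),
                           effect_sizes = c(mutation = 0, expression = 0,
                                            essentiality = 0),
                           seed = s)
    u <- generate_universe(250)
    tgt <- u[1:25]
    mats <- generate_sample_matrices(u, tgt, cfg)
    ess <- aggregate_samples(mats$essentiality)
    wilcox.test(ess[tgt], ess[setdiff(u, tgt)])$p.value
  }, 0)
  expect_lt(sum(pvals < 0.05), 5)
})

test_that("out-of-range mutation rates are clipped with a warning", {
  cfg <- scenario_config(n_genes = 100L, n_targets = 10L,
                         n_samples = c(mutation = 3L, expression = 2L,
                                       essentiality = 2L),
                         effect_sizes = c(mutation = 30, expression = 0,
                                          essentiality = 0),
                         seed = 1)
  u <- generate_universe(100)
  expect_warning(generate_sample_matrices(u, u[1:10], cfg), "clipped")
})

test_that("aggregation rules: mean for mutation, median otherwise", {
  m <- matrix(c(1, 0, 0, 1), nrow = 1, dimnames = list("G1", NULL))
  attr(m, "data_type") <- "mutation"
  expect_equal(unname(aggregate_samples(m)), 0.5)

  e <- matrix(c(1.0, 9.0, 2.0), nrow = 1, dimnames = list("G1", NULL))
  attr(e, "data_type") <- "expression"
  expect_equal(unname(aggregate_samples(e)), 2.0)

  s <- matrix(c(-1.0, -1.0), nrow = 1, dimnames = list("G1", NULL))
  attr(s, "data_type") <- "essentiality"
  expect_equal(unname(aggregate_samples(s)), -1.0)

  expect_error(aggregate_samples(matrix(1, 1, 1)), "data_type")
  bad <- matrix(numeric(0), nrow = 2, ncol = 0)
  attr(bad, "data_type") <- "expression"
  expect_error(aggregate_samples(bad), "sample")
})

test_that("identical configs reproduce identical scenarios", {
  cfg <- scenario_config(n_genes = 250L, n_targets = 10L, mean_degree = 4,
                         n_samples = c(mutation = 5L, expression = 5L,
                                       essentiality = 5L), seed = 13)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$features, s2$features)
  expect_identical(igraph::as_edgelist(s1$network),
                   igraph::as_edgelist(s2$network))
  expect_identical(s1$targets, s2$targets)
  cfg$seed <- 14L
  s3 <- simulate_scenario(cfg)
  expect_false(identical(s1$features, s3$features))
})

test_that("scenarios too small for ten disjoint negative sets are rejected", {
  cfg <- scenario_config(n_genes = 100L, n_targets = 10L, seed = 1)
  expect_error(simulate_scenario(cfg), "negative sets")
})
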