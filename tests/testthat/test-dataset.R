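test_that("positive set combines typed drug targets with driver genes", {
  rec <- data.frame(gene = c("A", "B"), drug = "d1",
                    interaction_type = c("inhibitor", NA))
  expect_equal(as.character(build_positive_set(rec, driver_genes = "C")),
               c("A", "C"))
  # drivers overlapping drug targets counted once
  expect_equal(as.character(build_positive_set(rec, driver_genes = "A")), "A")
  rec$interaction_type <- c("", NA)
  expect_error(build_positive_set(rec), "empty")
  expect_error(build_positive_set(data.frame(gene = "A")), "columns")
})

test_that("negative sets are disjoint, sized and seed-deterministic", {
  u <- sprintf("G%03d", 1:200)
  pos <- u[1:10]
  ns <- sample_negative_sets(u, pos, k = 10, seed = 3)
  expect_length(ns, 10)
  expect_true(all(lengths(ns) == 10))
  all_neg <- unlist(ns)
  expect_equal(length(unique(all_neg)), 100) # pairwise disjoint
  expect_length(intersect(all_neg, pos), 0)
  ns2 <- sample_negative_sets(u, pos, k = 10, seed = 3)
  expect_identical(unclass(ns)[1:10], unclass(ns2)[1:10])
  expect_error(sample_negative_sets(u[1:105], pos, k = 10, seed = 1), "100")
})

test_that("feature assembly drops incomplete genes and keeps column order", {
  primary <- data.frame(gene = sprintf("G%d", 1:5),
                        mutation_rate = c(0.1, 0.2, NA, 0.4, 0.5),
                        expression = c(1, NA, 3, 4, 5),
                        essentiality = c(-1, 0, 1, 0, -2))
  tab <- suppressMessages(assemble_feature_table(primary))
  expect_equal(nrow(tab), 3)
  expect_equal(names(tab), c("gene", "mutation_rate", "expression",
                             "essentiality"))

  emb <- matrix(rnorm(8), 4, 2, dimnames = list(sprintf("G%d", c(1, 2, 4, 5)),
                                                c("net_emb_1", "net_emb_2")))
  tab2 <- suppressMessages(assemble_feature_table(primary, emb))
  # G3 lacks mutation, G2 lacks expression; all others have embeddings
  expect_setequal(tab2$gene, c("G1", "G4", "G5"))
  expect_equal(ncol(tab2), 6)

  emb2 <- emb[1:2, , drop = FALSE]
  tab3 <- suppressMessages(assemble_feature_table(primary, emb2))
  expect_setequal(tab3$gene, "G1")

  primary$mutation_rate[1] <- 2
  expect_error(suppressMessages(assemble_feature_table(primary)), "\\[0, 1\\]")
})

test_that("stratified split follows per-class rounding and the seed", {
  d <- toy_dataset(n_per_class = 20, split = FALSE)
  s <- stratified_split(d, seed = 1)
  expect_equal(as.vector(table(s$label, s$split)["target", c("train", "test")]),
               c(14, 6))
  expect_equal(as.vector(table(s$label, s$split)["non_target", "train"]), 14)

  d39 <- toy_dataset(n_per_class = 39, split = FALSE)
  s39 <- stratified_split(d39, seed = 2)
  expect_equal(sum(s39$split == "train" & s39$label == "target"), 27)
  expect_equal(sum(s39$split == "test" & s39$label == "target"), 12)

  s_rep <- stratified_split(d, seed = 1)
  expect_identical(s$split, s_rep$split)

  tiny <- d[c(1, 21), ]
  expect_error(stratified_split(tiny, seed = 1), "at least 2")
})

test_that("the ten datasets obey the structural contracts", {
  ds <- tiny_datasets()
  sc <- tiny_scenario()
  expect_length(ds, 10)
  pos_rows <- lapply(ds, function(d) sort(d$gene[d$label == "target"]))
  for (i in seq_along(ds)) {
    d <- ds[[i]]
    expect_equal(sum(d$label == "target"), sum(d$label == "non_target"))
    tr <- table(d$label, d$split)
    # class balance within one gene in each split
    expect_lte(abs(tr["target", "train"] - tr["non_target", "train"]), 1)
    expect_lte(abs(tr["target", "test"] - tr["non_target", "test"]), 1)
    expect_setequal(d$split, c("train", "test"))
    # positives identical across the ten datasets
    expect_identical(pos_rows[[i]], pos_rows[[1]])
  }
  # negatives never repeat across the ten datasets
  neg_rows <- unlist(lapply(ds, function(d) d$gene[d$label == "non_target"]))
  expect_equal(anyDuplicated(neg_rows), 0)
})

test_that("dataset building validates feature coverage", {
  sc <- tiny_scenario()
  negs <- tiny_negatives()
  expect_error(build_datasets(sc$feature_table, c(sc$targets, "NOPE"), negs),
               "positives")
})
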