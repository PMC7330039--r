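test_that("edge lists are parsed with dedup, self-loop removal and universes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "A\tA"), f)
  g <- suppressMessages(load_edge_list(f))
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::ecount(g), 1)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  g2 <- load_edge_list(empty, universe = sprintf("U%d", 1:5))
  expect_equal(igraph::vcount(g2), 5)
  expect_equal(igraph::ecount(g2), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "A\tB\tC"), bad)
  expect_error(load_edge_list(bad), "line 2")
  expect_error(load_edge_list(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("edge list writing round-trips", {
  sc <- tiny_scenario()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(sc$network, f)
  g <- suppressMessages(load_edge_list(f, universe = sc$universe))
  expect_equal(igraph::ecount(g), igraph::ecount(sc$network))
  expect_setequal(igraph::V(g)$name, sc$universe)
})

test_that("diffusion walks cover forced and exhausted subgraphs", {
  path <- igraph::make_graph(~ A - B)
  w <- generate_walks(path, walks_per_node = 1, subgraph_size = 2, seed = 1)
  expect_equal(w$sequences[[1]], c("A", "B", "A"))

  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("C", paste0("L", 1:5))
  w2 <- generate_walks(star, walks_per_node = 1, subgraph_size = 6, seed = 2)
  expect_setequal(unique(w2$sequences[[1]]), igraph::V(star)$name)

  expect_error(generate_walks(path, subgraph_size = 1), "subgraph_size")
})

test_that("walk sequences stay inside the source's connected component", {
  sc <- tiny_scenario()
  w <- suppressMessages(generate_walks(sc$network, walks_per_node = 2,
                                       subgraph_size = 10, seed = 3))
  comp <- igraph::components(sc$network)$membership
  for (s in w$sequences[seq(1, length(w$sequences), by = 17)]) {
    expect_equal(length(unique(comp[s])), 1)
  }
})

test_that("every non-isolated node is a walk source walks_per_node times", {
  sc <- tiny_scenario()
  wpn <- 3
  w <- suppressMessages(generate_walks(sc$network, walks_per_node = wpn,
                                       subgraph_size = 8, seed = 4))
  sources <- vapply(w$sequences, `[`, "", 1)
  counts <- table(sources)
  deg <- igraph::degree(sc$network)
  expect_true(all(counts[names(deg)[deg >= 1]] >= wpn))
  # isolated nodes appear as singleton sequences
  iso <- names(deg)[deg == 0]
  if (length(iso)) {
    lens <- lengths(w$sequences[sources %in% iso])
    expect_true(all(lens == 1))
  }
})

test_that("embedding separates two disjoint cliques", {
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  igraph::V(g)$name <- sprintf("N%02d", 1:20)
  emb <- embed_network(g, d = 8, walks_per_node = 10, subgraph_size = 10,
                       epochs = 5, seed = 1)
  expect_equal(dim(emb), c(20, 8))
  expect_equal(colnames(emb), sprintf("net_emb_%d", 1:8))
  cs <- emb / sqrt(rowSums(emb^2))
  S <- cs %*% t(cs)
  blk <- rep(1:2, each = 10)
  intra <- mean(S[outer(blk, blk, "==") & upper.tri(S)])
  inter <- mean(S[outer(blk, blk, "!=") & upper.tri(S)])
  expect_gt(intra, inter)
})

test_that("a corpus of singleton sequences trains to the zero matrix", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- paste0("I", 1:4)
  corpus <- suppressMessages(generate_walks(g, walks_per_node = 2,
                                            subgraph_size = 5, seed = 1))
  emb <- suppressMessages(train_embedding(corpus, d = 6, seed = 1))
  expect_true(all(emb == 0))
  expect_equal(dim(emb), c(4, 6))
})

test_that("embedding training is deterministic and validates arguments", {
  g <- igraph::sample_gnp(40, 0.15)
  igraph::V(g)$name <- sprintf("V%02d", 1:40)
  corpus <- suppressMessages(generate_walks(g, walks_per_node = 3,
                                            subgraph_size = 8, seed = 5))
  e1 <- suppressMessages(train_embedding(corpus, d = 8, epochs = 2, seed = 9))
  e2 <- suppressMessages(train_embedding(corpus, d = 8, epochs = 2, seed = 9))
  expect_identical(e1, e2)
  e3 <- suppressMessages(train_embedding(corpus, d = 8, epochs = 2, seed = 10))
  expect_false(identical(e1, e3))
  expect_error(train_embedding(corpus, d = 0), "d must be")
})

test_that("embedding files round-trip through TSV", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("A", "B", "C"), sprintf("net_emb_%d", 1:4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_embedding(m, f)
  m2 <- read_embedding(f)
  expect_equal(m2, m, tolerance = 1e-12)
})
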