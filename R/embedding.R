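#' Generate diffusion-walk sequences from an interaction network
#'
#' For each node and each of `walks_per_node` repeats, grows a random
#' diffusion subgraph starting from that node — repeatedly picking a uniformly
#' random already-included node and a uniformly random not-yet-included
#' neighbor of it — until `subgraph_size` nodes are included or the reachable
#' neighborhood is exhausted. The grown subgraph is a tree; the emitted
#' sequence is its Euler circuit (each tree edge traversed twice), so nearby
#' nodes co-occur in short windows of the sequence. Isolated nodes yield
#' singleton sequences (counted and logged).
#'
#' @param network an undirected igraph object with named vertices.
#' @param walks_per_node sequences started from each node (default 10).
#' @param subgraph_size target number of nodes per diffusion subgraph
#'   (default 40; must be at least 2).
#' @param seed integer seed; the corpus is deterministic given the seed.
#' @return An object of class `walk_corpus`: a list with `sequences` (list of
#'   character vectors of gene symbols), `nodes` (all network vertices) and
#'   the walk parameters.
#' @export
generate_walks <- function(network, walks_per_node = 10L, subgraph_size = 40L,
                           seed = 1L) {
  if (subgraph_size < 2) stop_invalid("subgraph_size must be >= 2")
  if (walks_per_node < 1) stop_invalid("walks_per_node must be >= 1")
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) stop_invalid("network vertices must be named")
  adj <- igraph::as_adj_list(network, mode = "all")
  deg <- lengths(adj)
  neighbors <- unlist(lapply(adj, as.integer), use.names = FALSE)
  if (is.null(neighbors)) neighbors <- integer(0)
  offsets <- c(0L, cumsum(deg))
  n_isolated <- sum(deg == 0)
  if (n_isolated > 0) {
    log_note("generate_walks: %d isolated node(s) yield singleton sequences",
             n_isolated)
  }
  idx_walks <- with_seed(seed,
    diffusion_walks_cpp(as.integer(offsets), neighbors - 1L,
                        as.integer(walks_per_node), as.integer(subgraph_size)))
  sequences <- lapply(idx_walks, function(s) nodes[s])
  structure(list(sequences = sequences, nodes = nodes,
                 walks_per_node = as.integer(walks_per_node),
                 subgraph_size = as.integer(subgraph_size), seed = as.integer(seed)),
            class = "walk_corpus")
}

#' Train a skip-gram embedding on a walk corpus
#'
#' Learns fixed-dimension node vectors with a skip-gram
#' negative-sampling objective over the walk sequences, so nodes that co-occur
#' in diffusion subgraphs receive similar vectors. Training is
#' single-threaded and draws all randomness from R's RNG, making the result
#' deterministic for a given corpus and seed. Nodes that never take part in a
#' (center, context) pair — e.g. isolated nodes with only singleton sequences
#' — receive the zero vector and their count is logged.
#'
#' @param corpus a `walk_corpus` from [generate_walks()].
#' @param d embedding dimension (default 32).
#' @param window maximum skip-gram window (default 5; the effective window is
#'   shrunk uniformly at random per position, as usual for word2vec).
#' @param epochs passes over the corpus (default 5).
#' @param negative negative samples per positive pair (default 5).
#' @param alpha initial learning rate, decayed linearly (default 0.025).
#' @param seed integer seed.
#' @return Numeric matrix with one row per network node (gene rownames) and
#'   `d` columns named `net_emb_1` ... `net_emb_d`.
#' @export
train_embedding <- function(corpus, d = 32L, window = 5L, epochs = 5L,
                            negative = 5L, alpha = 0.025, seed = 1L) {
  stopifnot(inherits(corpus, "walk_corpus"))
  if (d < 1) stop_invalid("embedding dimension d must be >= 1")
  if (length(corpus$sequences) == 0) stop_invalid("corpus is empty")
  nodes <- corpus$nodes
  seqs <- lapply(corpus$sequences, function(s) match(s, nodes))
  emb <- with_seed(seed,
    sgns_train_cpp(seqs, length(nodes), as.integer(d), as.integer(window),
                   as.integer(epochs), as.integer(negative), alpha))
  rownames(emb) <- nodes
  colnames(emb) <- sprintf("net_emb_%d", seq_len(d))
  n_zero <- sum(rowSums(emb != 0) == 0)
  if (n_zero > 0) {
    log_note("train_embedding: %d node(s) without context pairs got zero vectors",
             n_zero)
  }
  emb
}

#' Embed an interaction network (walks + skip-gram in one step)
#'
#' Convenience wrapper running [generate_walks()] then [train_embedding()].
#' The embedding features are global (independent of cancer type) and are
#' joined to every per-cancer dataset downstream.
#'
#' @inheritParams generate_walks
#' @inheritParams train_embedding
#' @return Gene-by-`d` embedding matrix.
#' @export
#' @examples
#' g <- igraph::sample_gnp(60, 0.1)
#' igraph::V(g)$name <- sprintf("G%02d", 1:60)
#' emb <- embed_network(g, d = 8, walks_per_node = 2, subgraph_size = 10,
#'                      epochs = 1, seed = 1)
#' dim(emb)
embed_network <- function(network, d = 32L, walks_per_node = 10L,
                          subgraph_size = 40L, window = 5L, epochs = 5L,
                          negative = 5L, alpha = 0.025, seed = 1L) {
  corpus <- generate_walks(network, walks_per_node = walks_per_node,
                           subgraph_size = subgraph_size,
                           seed = derive_seed(seed, "walks"))
  train_embedding(corpus, d = d, window = window, epochs = epochs,
                  negative = negative, alpha = alpha,
                  seed = derive_seed(seed, "embedding"))
}
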