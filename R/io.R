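# Plain-text I/O helpers: UTF-8, tab-delimited, '.' decimal throughout.

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_file <- function(path) {
  if (!file.exists(path)) stop_invalid("input file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, fileEncoding = "UTF-8")
}

#' Read a two-column edge list into an interaction network
#'
#' Parses a tab-delimited file of gene symbol pairs (one undirected edge per
#' line, no header) into an undirected network. Self-loops and duplicate
#' edges (including reversed duplicates) are removed and their count logged.
#' Vertices are the union of the endpoint symbols and any supplied `universe`,
#' so genes without interactions become isolated nodes.
#'
#' @param path path to the edge-list file.
#' @param universe optional character vector of gene symbols to include as
#'   vertices even when absent from the edge list.
#' @return An undirected igraph object with named vertices.
#' @export
load_edge_list <- function(path, universe = NULL) {
  if (!file.exists(path)) stop_invalid("input file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad)) {
    stop_invalid("malformed edge list line ", bad[1], " in ", path,
                 ": expected 2 tab-separated fields, got ",
                 length(fields[[bad[1]]]))
  }
  el <- if (length(fields)) do.call(rbind, fields) else matrix(character(), 0, 2)
  nodes <- unique(c(el[, 1], el[, 2], universe))
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(el)) {
    g <- igraph::add_edges(g, rbind(match(el[, 1], nodes), match(el[, 2], nodes)))
    before <- igraph::ecount(g)
    g <- igraph::simplify(g)
    removed <- before - igraph::ecount(g)
    if (removed > 0) {
      log_note("load_edge_list: removed %d self-loop/duplicate edge(s)", removed)
    }
  }
  g
}

#' Write a network as a two-column edge list
#'
#' @param network an undirected igraph object with named vertices.
#' @param path output path (tab-delimited, no header).
#' @return The path, invisibly.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Write a scenario as a bundle of plain-text input files
#'
#' Writes the primary feature table, the three sample matrices, the network
#' edge list, the target gene list and the scenario configuration (flat
#' key=value file) into a directory, producing a complete file-based input
#' bundle for the pipeline.
#'
#' @param scenario result of [simulate_scenario()].
#' @param dir output directory (created if missing).
#' @param holdout_targets optional character vector of planted targets to
#'   withhold from the written positive list; written separately to
#'   `heldout_targets.txt` for recovery analyses.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir, holdout_targets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(scenario$features, file.path(dir, "features_primary.tsv"))
  for (nm in names(scenario$matrices)) {
    m <- scenario$matrices[[nm]]
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("gene", sprintf("sample_%d", seq_len(ncol(m))))
    write_tsv_file(df, file.path(dir, sprintf("samples_%s.tsv", nm)))
  }
  write_edge_list(scenario$network, file.path(dir, "network_edges.tsv"))
  positives <- scenario$targets
  if (!is.null(holdout_targets)) {
    positives <- setdiff(positives, holdout_targets)
    writeLines(holdout_targets, file.path(dir, "heldout_targets.txt"))
  }
  writeLines(positives, file.path(dir, "targets.txt"))
  cfg <- scenario$config
  kv <- c(sprintf("n_genes=%d", cfg$n_genes),
          sprintf("n_targets=%d", cfg$n_targets),
          sprintf("n_samples_%s=%d", names(cfg$n_samples), cfg$n_samples),
          sprintf("effect_%s=%g", names(cfg$effect_sizes), cfg$effect_sizes),
          sprintf("mean_degree=%g", cfg$mean_degree),
          sprintf("n_communities=%d", cfg$n_communities),
          sprintf("n_informative_communities=%d", cfg$n_informative_communities),
          sprintf("target_affinity=%g", cfg$target_affinity),
          sprintf("community_mix=%g", cfg$community_mix),
          sprintf("informative_density=%g", cfg$informative_density),
          sprintf("seed=%d", cfg$seed))
  writeLines(kv, file.path(dir, "scenario_config.txt"))
  invisible(dir)
}

#' Write an embedding matrix as TSV
#'
#' @param embedding gene-by-dimension matrix with gene rownames.
#' @param path output path; columns are `gene`, `net_emb_1` ... `net_emb_d`.
#' @return The path, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(gene = rownames(embedding), embedding, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", sprintf("net_emb_%d", seq_len(ncol(embedding))))
  write_tsv_file(df, path)
}

#' Read an embedding matrix from TSV
#'
#' @param path a file written by [write_embedding()].
#' @return Gene-by-dimension numeric matrix with gene rownames.
#' @export
read_embedding <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}
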