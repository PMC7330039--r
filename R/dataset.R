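#' Build the positive (target) gene set
#'
#' Combines drug-target records with driver genes under the inclusion rule:
#' a gene qualifies through a drug-target record only when the record carries
#' interaction-type information (excluding untargeted chemotherapies and
#' off-target annotations); cancer driver genes are added unconditionally.
#' Duplicates are collapsed.
#'
#' @param drug_target_records data.frame with columns `gene`, `drug` and
#'   `interaction_type` (empty string or NA meaning "no interaction type
#'   available").
#' @param driver_genes character vector of cancer driver genes (may be empty).
#' @param cancer_label label recorded with the set.
#' @return Sorted character vector of positive genes with a `cancer_label`
#'   attribute.
#' @export
#' @examples
#' rec <- data.frame(gene = c("A", "B"), drug = "d1",
#'                   interaction_type = c("inhibitor", NA))
#' build_positive_set(rec, driver_genes = "C")  # A and C
build_positive_set <- function(drug_target_records, driver_genes = character(),
                               cancer_label = "cancer") {
  need <- c("gene", "drug", "interaction_type")
  if (!all(need %in% names(drug_target_records))) {
    stop_invalid("drug_target_records needs columns: ", paste(need, collapse = ", "))
  }
  it <- drug_target_records$interaction_type
  has_type <- !is.na(it) & nzchar(trimws(as.character(it)))
  positives <- sort(unique(c(drug_target_records$gene[has_type],
                             as.character(driver_genes))))
  if (length(positives) == 0) {
    stop_invalid("positive set is empty: no records with interaction type and no drivers")
  }
  attr(positives, "cancer_label") <- cancer_label
  positives
}

#' Sample disjoint negative (non-target) gene sets
#'
#' Draws `k` pairwise disjoint sets of non-target genes, each the size of the
#' positive set, sampled without replacement from the universe minus the
#' positives. Because true targets are assumed rare among protein-coding
#' genes, random genes are taken as negatives; using `k` disjoint sets (and
#' later averaging over them) reduces the impact of any single draw.
#'
#' @param universe character vector of candidate genes (typically the genes
#'   with complete feature data).
#' @param positives character vector of positive genes.
#' @param k number of sets (default 10).
#' @param seed integer seed; sampling is deterministic given the seed.
#' @return A list of `k` character vectors (class `negative_sets`), pairwise
#'   disjoint and disjoint from the positives.
#' @export
sample_negative_sets <- function(universe, positives, k = 10L, seed = 1L) {
  pool <- setdiff(universe, positives)
  size <- length(positives)
  if (size == 0) stop_invalid("positive set is empty")
  if (length(pool) < k * size) {
    stop_invalid("negative pool too small: need ", k * size,
                 " non-positive genes, have ", length(pool))
  }
  drawn <- with_seed(seed, sample(pool, k * size))
  sets <- split(drawn, rep(seq_len(k), each = size))
  names(sets) <- NULL
  structure(sets, class = "negative_sets", seed = as.integer(seed))
}

#' Assemble the per-gene feature table
#'
#' Inner-joins the primary features (mutation rate, expression, essentiality)
#' with the network embedding. Genes missing any primary feature value, or
#' lacking an embedding row, are dropped and the attrition is logged —
#' downstream models require complete 35-dimensional vectors.
#'
#' @param primary data.frame with columns `gene`, `mutation_rate`,
#'   `expression`, `essentiality` (values may be NA).
#' @param embedding optional gene-by-d embedding matrix with gene rownames;
#'   when NULL the table carries the 3 primary features only.
#' @param genes optional character vector restricting the output.
#' @return data.frame with `gene` plus 3 (or 3 + d) complete feature columns
#'   in canonical order.
#' @export
assemble_feature_table <- function(primary, embedding = NULL, genes = NULL) {
  need <- c("gene", "mutation_rate", "expression", "essentiality")
  if (!all(need %in% names(primary))) {
    stop_invalid("primary needs columns: ", paste(need, collapse = ", "))
  }
  tab <- primary[, need]
  if (!is.null(genes)) tab <- tab[tab$gene %in% genes, , drop = FALSE]
  n0 <- nrow(tab)
  complete <- stats::complete.cases(tab[, -1])
  ok <- tab$mutation_rate[complete] >= 0 & tab$mutation_rate[complete] <= 1
  if (any(!ok)) stop_invalid("mutation_rate outside [0, 1]")
  tab <- tab[complete, , drop = FALSE]
  if (!is.null(embedding)) {
    hit <- match(tab$gene, rownames(embedding))
    keep <- !is.na(hit) & apply(is.finite(embedding[hit, , drop = FALSE]), 1, all)
    keep[is.na(keep)] <- FALSE
    tab <- cbind(tab[keep, , drop = FALSE],
                 as.data.frame(embedding[hit[keep], , drop = FALSE]))
  }
  dropped <- n0 - nrow(tab)
  if (dropped > 0) {
    log_note("assemble_feature_table: dropped %d gene(s) with incomplete data", dropped)
  }
  if (nrow(tab) == 0) stop_invalid("no genes with complete feature data")
  rownames(tab) <- NULL
  tab
}

#' Stratified train/test split of a balanced labeled dataset
#'
#' Assigns `round(train_frac * class size)` genes of each class to the
#' training split (round-half-even, R's default rounding) and the remainder
#' to the test split, preserving the class balance in both. Deterministic
#' for a given seed.
#'
#' @param dataset data.frame with a `label` column (factor or character with
#'   two classes).
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed.
#' @return The dataset with an added `split` column (`"train"`/`"test"`).
#' @export
stratified_split <- function(dataset, train_frac = 0.7, seed = 1L) {
  if (!"label" %in% names(dataset)) stop_invalid("dataset needs a 'label' column")
  classes <- split(seq_len(nrow(dataset)), dataset$label)
  if (any(lengths(classes) < 2)) {
    stop_invalid("each class needs at least 2 members to split")
  }
  dataset$split <- "test"
  with_seed(seed, {
    for (idx in classes) {
      n_train <- round(train_frac * length(idx))
      dataset$split[sample(idx, n_train)] <- "train"
    }
  })
  if (!all(c("train", "test") %in% dataset$split)) {
    stop_invalid("train_frac leaves an empty split")
  }
  dataset
}

#' Build the ten balanced labeled datasets for one cancer type
#'
#' For each negative set, stacks the positive genes (label `target`) and that
#' set's negatives (label `non_target`), joins the feature table, and applies
#' a stratified 70/30 split with a per-set sub-seed derived from the master
#' seed. Positives are identical across the ten datasets; negatives never
#' repeat across them.
#'
#' @param features complete feature table from [assemble_feature_table()].
#' @param positives character vector of positive genes (must all be present
#'   in `features`).
#' @param negatives a `negative_sets` collection.
#' @param train_frac training fraction (default 0.7).
#' @param seed master seed; per-set split seeds are derived from it.
#' @return List of data.frames (gene, label, split, features), one per
#'   negative set.
#' @export
build_datasets <- function(features, positives, negatives, train_frac = 0.7,
                           seed = 1L) {
  if (!all(positives %in% features$gene)) {
    stop_invalid("all positives must be present in the feature table")
  }
  lapply(seq_along(negatives), function(i) {
    neg <- negatives[[i]]
    if (!all(neg %in% features$gene)) {
      stop_invalid("negative set ", i, " contains genes missing from the feature table")
    }
    genes <- c(positives, neg)
    d <- features[match(genes, features$gene), , drop = FALSE]
    d <- cbind(gene = d$gene,
               label = factor(rep(c("target", "non_target"),
                                  c(length(positives), length(neg))),
                              levels = c("non_target", "target")),
               d[, -1, drop = FALSE])
    d <- stratified_split(d, train_frac = train_frac,
                          seed = derive_seed(seed, "split", i))
    attr(d, "negative_set") <- i
    rownames(d) <- NULL
    d
  })
}

feature_columns <- function(dataset) {
  setdiff(names(dataset), c("gene", "label", "split"))
}
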