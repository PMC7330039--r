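#' Mann-Whitney-Wilcoxon test for one feature
#'
#' Two-sample rank test of targets versus non-targets. The U statistic counts
#' pairs where the positive value exceeds the negative one (ties count one
#' half). The two-sided p value uses the tie-corrected normal approximation;
#' for small samples (both groups of size at most 8, no ties) the exact
#' distribution is used.
#'
#' @param pos_values numeric feature values of the positive class.
#' @param neg_values numeric feature values of the negative class.
#' @return List with `U` and `p`.
#' @export
#' @examples
#' mann_whitney(c(3, 4, 5), c(1, 2, 3))$U  # 8.5
mann_whitney <- function(pos_values, neg_values) {
  if (length(pos_values) < 1 || length(neg_values) < 1) {
    stop_invalid("both groups need at least one value")
  }
  has_ties <- anyDuplicated(c(pos_values, neg_values)) > 0
  exact <- length(pos_values) <= 8 && length(neg_values) <= 8 && !has_ties
  wt <- suppressWarnings(
    wilcox.test(pos_values, neg_values, alternative = "two.sided",
                exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: the adjusted value for the i-th
#' smallest p is `min over j >= i of m * p_(j) / j`, clipped at 1, returned
#' in the original order.
#'
#' @param pvals numeric vector of p values in \[0, 1\].
#' @return Adjusted q values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop_invalid("p values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Univariate two-class screening of all features
#'
#' Tests each feature for a distributional difference between targets and
#' non-targets on the full dataset (train + test), with the ten negative sets
#' pooled and the positives counted once. BH adjustment is applied across the
#' features of this cancer type.
#'
#' @param features complete feature table ([assemble_feature_table()]).
#' @param positives character vector of positive genes.
#' @param negatives a `negative_sets` collection (or any list of character
#'   vectors); pooled for the test.
#' @return data.frame (class `univariate_report`) with one row per feature:
#'   `feature`, `U`, `p`, `q`; attributes `n_pos`, `n_neg`.
#' @export
univariate_screen <- function(features, positives, negatives) {
  neg_pool <- unique(unlist(negatives))
  pos <- features[match(intersect(positives, features$gene), features$gene), ]
  neg <- features[match(intersect(neg_pool, features$gene), features$gene), ]
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    stop_invalid("both classes must be covered by the feature table")
  }
  feats <- setdiff(names(features), "gene")
  res <- lapply(feats, function(f) mann_whitney(pos[[f]], neg[[f]]))
  out <- data.frame(feature = feats,
                    U = vapply(res, `[[`, 0, "U"),
                    p = vapply(res, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  attr(out, "n_pos") <- nrow(pos)
  attr(out, "n_neg") <- nrow(neg)
  class(out) <- c("univariate_report", "data.frame")
  out
}
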