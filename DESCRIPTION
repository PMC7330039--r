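Package: targetrank
Title: Genome-Wide Ranking of Candidate Cancer Drug Targets by Ensemble Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate therapeutic target genes for a cancer type by
    supervised classification of genes into targets and non-targets. Per-gene
    mutation rate, expression and essentiality features are combined with a
    32-dimensional embedding of the gene-gene interaction network learned from
    diffusion-walk sequences. Known targets are contrasted against ten disjoint
    balanced samples of non-target genes; features are screened against a
    label-permutation null distribution of random-forest importances; five
    classifier families are tuned by cross-validation and compared by test-set
    AUROC; and the best method, retrained on all labeled data, yields an
    ensemble ranking of every unlabeled gene. A seeded synthetic-data generator
    produces gene universes, sample-level omics matrices and modular scale-free
    interaction networks with planted target signal for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    ranger,
    e1071,
    xgboost,
    nnet,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
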