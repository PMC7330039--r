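---
title: "Ranking candidate cancer drug targets: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate cancer drug targets: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the modeling approach

Choosing which gene to pursue as a drug target is one of the costliest
decisions in oncology drug discovery. `targetrank` frames target
identification as supervised, per-cancer-type classification: genes known to
be targets of approved drugs (restricted to drug–gene records that carry
interaction-type information, to exclude untargeted chemotherapies and
off-target annotations) plus cancer driver genes form the positive class,
and randomly sampled protein-coding genes stand in for the negative class.
Because genuine targets are rare among ~17,000 protein-coding genes, a
random sample is an acceptable negative set; to keep any single unlucky draw
from dominating the results, **ten pairwise disjoint negative sets** of the
same size as the positive set are drawn, and every downstream statistic is
an average over the ten resulting balanced datasets.

Each gene is described by 35 features:

* **mutation rate** — the mean of binary per-sample mutation calls for the
  cancer cohort, a value in $[0, 1]$;
* **expression** — the median expression over cohort samples (log-like
  scale);
* **essentiality** — the median CRISPR knock-out sensitivity (CERES-like)
  score over cell lines of the lineage, centered near 0 with a negative tail
  for essential genes;
* **32 network-embedding coordinates** — a learned representation of each
  gene's neighborhood in the gene–gene interaction network. These are global
  (cancer-type independent) and joined to every per-cancer dataset.

## Network embedding

The embedding is learned from *diffusion-walk* sequences. For every node we
repeatedly (default `walks_per_node = 10`) grow a random diffusion subgraph:
starting from the node, we pick a uniformly random already-included node and
a uniformly random not-yet-included neighbor of it, until
`subgraph_size = 40` nodes are included or the reachable neighborhood is
exhausted. The grown subgraph is a tree by construction; the emitted
sequence is its Euler circuit (each edge traversed twice), so graph-proximal
nodes co-occur within short windows. A skip-gram model with negative
sampling (dimension `d = 32`, `window = 5`, `epochs = 5`, 5 negative samples,
initial learning rate 0.025 with linear decay) is then trained on the
corpus. The walk/window/epoch values follow the common regime for
sequence-based node embeddings of protein-interaction-scale graphs and are
all configurable; `d = 32` matches the dimensionality previously found
adequate for protein-interaction networks. Training is single-threaded with
all randomness drawn from R's RNG, so a seed fully reproduces the matrix;
isolated nodes yield singleton sequences and receive the zero vector (their
count is logged).

We deliberately plant the synthetic network class signal in *community
membership* rather than degree, so that what the embedding must capture is
neighborhood identity — a trivial degree feature would not help. The package
makes no attempt to interpret individual embedding dimensions.

## Feature screening and selection

Two complementary views of feature informativeness are computed:

* **Univariate** — a Mann–Whitney–Wilcoxon test per feature, targets versus
  non-targets, on the full data (train + test) with the ten negative sets
  pooled and positives counted once. The U statistic counts pairs where the
  target value exceeds the non-target value (ties half); p values use the
  tie-corrected normal approximation (exact distribution when both groups
  have at most 8 values and no ties). Benjamini–Hochberg correction is
  applied across the 35 features of one cancer type — the family matches the
  per-feature, per-cancer reporting, and is the package's choice since a
  broader family (e.g. across cancer types) is equally defensible.
  Two-sided alternatives are used throughout.
* **Multivariate** — a random-forest permutation-null importance. For each
  of the ten training splits, a forest is fit on the true labels and its
  impurity-decrease (information-gain) importances recorded; the labels are
  then shuffled `n_shuffles = 100` times, a forest refit per shuffle (fresh
  derived seed each time), and each feature's real importance is expressed
  as a z-score against its own null distribution. z-scores are averaged over
  the ten negative sets, and features with average $z \ge 0.5$ (boundary
  inclusive) are retained. The importance forest is fixed at 100 trees with
  default depth rather than tuned: the quantity of interest is a *relative*
  importance, its stability comes from averaging 10 sets × 100 shuffles, and
  a modest forest keeps the 1,000-fit null affordable. A degenerate null
  (zero SD) maps to a capped sentinel z of ±10 with a warning; finite z
  values are clipped at the same magnitude.

Only training-split rows enter the multivariate selection, so the test
split never influences which features the models see.

## Classifiers, tuning and evaluation

Five families are benchmarked per negative set, each tuned by stratified
5-fold cross-validation on the training split with AUROC as the selection
metric (the same metric used for final evaluation, keeping one objective
throughout). Ties resolve to the earlier grid row; grids are ordered
simple-first. Default search spaces (all overridable):

| method | grid |
|---|---|
| random forest | trees {100, 300, 500} × depth {3, 5, unlimited} × mtry {√p, p} |
| logistic regression | none (no tunable hyperparameters) |
| SVM | linear: cost {0.1, 1, 10}; RBF: cost {0.1, 1, 10} × bandwidth {0.5, 1, 2} × scale heuristic $1/(p\,\overline{\mathrm{var}})$ |
| gradient boosting | learning rate {0.01, 0.1} × rounds {100, 300} × depth {3, 5} |
| neural network | hidden units {8, 16} × weight decay {0.1, 0.01} |

SVM probabilities come from the cross-validated sigmoid calibration layer of
the underlying implementation — ranking requires probabilities, not margins.
The neural network is a single-hidden-layer perceptron on standardized
inputs with weight-decay regularization and up to 500 iterations: for
balanced tabular datasets of a few dozen to a few hundred rows and at most
35 features, a compact, strongly regularized architecture is the appropriate
regime, and weight decay provides the regularization role that dropout and
batch normalization play in deeper networks. The gradient-boosting grid is
adapted to the tree-booster parameterization (no "unlimited" depth; column
subsampling left at 1).

Each method's ten test-split AUROCs are averaged; the best method (argmax of
the mean, ties to the first method in the declared order) is retrained on
the *full* (train + test) rows of each negative-set dataset with the
hyperparameters tuned on the training split, giving an ensemble of ten
related models that differ only in the negatives they saw.

## Genome-wide ranking

The ensemble predicts a target probability for every gene with complete
data except the positives. A gene belonging to negative set $i$ was seen as
a labeled non-target by model $i$, so only the other nine models contribute
to its average — using all ten would let a training label leak into that
gene's score. Genes are ranked by decreasing mean probability with ties
broken alphabetically by symbol (deterministic output files), and the mean
probabilities are also reported as z-scores over the ranked genes so that
rankings from different cancer types share a scale; standardization is
applied to the ensemble *mean* (standardizing per model before averaging is
an equally defensible alternative; the ranking itself is unchanged by any
monotone choice). The fraction of genes above probability 0.5 is attached
as a diagnostic only — balanced training inflates absolute probabilities,
and the scientific output is the ranking, not a calibrated probability.
Optionally, a ranking can be validated against per-gene citation counts by
Spearman correlation on a random sample of 1,000 ranked genes (genes absent
from the citation table count as 0, logged).

## The synthetic-data generator

Real inputs (tumor cohorts, dependency screens, curated interactions) are
file-based and out of scope for retrieval, so the package ships a seeded
generator that reproduces the statistical structure the analysis relies on:

* **mutation** — gene-level Bernoulli rates from Beta(1.5, 25) (mode ≈ 0.02,
  SD ≈ 0.044), mimicking somatic mutation sparsity; planted targets are
  shifted by `effect × SD` and clipped to $[0,1]$ with a warning (clipping,
  not resampling — a small, documented bias in extreme configurations);
  per-sample binary calls are then drawn and aggregated by the mean.
* **expression** — gene-level means from N(5, 2) on a log-like scale with
  unit per-sample noise, aggregated by the median.
* **essentiality** — 90% of genes near 0 (N(−0.1, 0.25)), 10% strongly
  essential (N(−1, 0.3)), echoing CERES score semantics; per-sample noise SD
  0.15; the default target shift is **zero**, making essentiality the
  planted-uninformative feature.
* **network** — a degree-corrected block model: Pareto(α = 2.5) node
  propensities (heavy-tailed degrees), `n_communities = 8` with
  within-community affinity ×8, two designated informative communities with
  an extra ×2 density, and edge probabilities rescaled so the expected mean
  degree is met. Targets are assigned to informative communities with
  probability `target_affinity`, planting the network signal in membership,
  not degree.

Default cohort sizes are 150 samples for mutation and expression and 25 for
essentiality — the order of magnitude of a TCGA cohort and of a DepMap
lineage respectively. Sample counts, effect sizes and wiring are all set in
`scenario_config()`. What the generator does *not* emulate: mutation
signatures, co-expression structure, cancer-subtype heterogeneity, and the
literature-coverage bias of curated interaction databases. Passing the
validation suite therefore demonstrates that the pipeline recovers the kind
of signal it assumes, not that real cancer data contain that signal.

## Named study conditions and problem sizes

Three fixed conditions drive the validation suite (`fixture_scenario()`):

* **null** — 2,400 genes, 100 planted "targets", all effect sizes 0, random
  wiring. Every downstream discriminative statistic should calibrate to
  chance: test AUROC 0.5, permutation-null z centered at 0. The larger
  positive class is variance control: with 30 + 30 test rows per split the
  per-set AUROC standard error is ≈ 0.076, so the mean over ten sets is
  stable enough for a meaningful ±0.06 calibration band.
* **signal** — 2,000 genes, 80 planted targets (60 labeled positives, 20
  withheld), mutation +2 SD, expression +1.5 SD, essentiality 0, strong
  community wiring. Selection must retain mutation and expression and drop
  essentiality; models must reach high test AUROC; the 20 withheld targets
  must rank far above random genes in the final ranking even though they
  were never labeled.
* **community** — as `signal` but with the signal moved into the network
  (mutation +0.5 SD only, `target_affinity = 0.95`): the condition under
  which the extended feature set must outperform the primary-only models.

These sizes — a few thousand genes, 10 × 100-shuffle importance nulls,
5-fold tuning over the default grids — are the package's chosen validation
scale: large enough for stable averages over ten negative sets, small enough
to run routinely on one CPU.

## Numerical and degenerate-case choices

* 70/30 split counts use `round()` (round-half-even) per class; both splits
  must be non-empty and classes may differ by at most one gene per split.
* One master seed expands into per-stage, per-replicate sub-seeds by fixed
  offsets, so a single integer reproduces the whole ten-replicate design,
  including the label shuffles.
* The negative-sampling pool is filtered to feature-complete genes *before*
  sampling (the alternative — drop incomplete negatives afterwards — would
  break the exact class balance).
* AUROC is computed from ranks (ties half), which equals the exhaustive
  pairwise count; it is tested against that oracle to 1e-12.
* Walks from isolated nodes are singletons; an all-singleton corpus trains
  to an all-zero embedding rather than crashing.
* Genes missing any primary feature or embedding row are dropped at
  assembly with a logged count, mirroring the positives-with-data attrition
  that real multi-omic joins exhibit.

## Known limitations

* The synthetic marginals are stipulated, not fitted to real cohorts; no
  claim is made that effect sizes of +2 SD correspond to any particular
  cancer type.
* Impurity-based importances are biased toward high-cardinality features;
  here all features are continuous, which limits but does not remove the
  concern. The permutation null absorbs most of the remaining bias because
  each feature is compared to *its own* shuffled-label distribution.
* Probability outputs are not calibrated (balanced training guarantees
  inflated absolute probabilities); only the ranking is meaningful.
* With strong class signal the label-shuffle null can be degenerate for a
  dominant feature (zero SD across shuffles); the capped z of ±10 keeps
  selection behavior correct but the magnitude is then a sentinel, not a
  measurement.
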