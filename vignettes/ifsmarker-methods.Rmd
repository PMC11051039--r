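---
title: "Incremental feature selection for marker discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental feature selection for marker discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Given a labeled expression matrix — cells in rows, genes in columns,
log-normalized nonnegative values, one class label per cell (the motivating
setting is lung single-cell data with *active smoker / former smoker / never
smoker* labels) — we want three things at once:

1. a short list of genes that discriminate the classes,
2. an estimate of how many top-ranked genes are actually needed, and
3. human-readable threshold rules that say *how* those genes separate the
   classes.

The pipeline answers these with, respectively, multi-algorithm feature
ranking, incremental feature selection (IFS), and decision-tree rule
extraction. Class imbalance — typically one dominant class, e.g. a
68% "never" majority — is handled by SMOTE oversampling inside the
evaluation loop, and performance is scored with imbalance-aware metrics
(weighted F1, multiclass MCC).

## Feature ranking

`rank_features()` produces a complete ordering of the genes under one of
eight importance criteria: random forest and extremely randomized trees
(impurity-decrease importance, via `ranger`), level-wise and leaf-wise
gradient boosting (total-gain importance, via `xgboost`; the leaf-wise
variant grows loss-guided trees over histogram bins), an oblivious-tree
gradient booster and a multiclass SAMME AdaBoost implemented in this
package, one-vs-rest L1-penalized logistic regression (largest absolute
coefficient across classes, via `glmnet`), and Monte Carlo feature
selection (MCFS), implemented from scratch.

Each ranker runs on the full dataset — lists are produced once, before any
cross-validation — and with a pinned, documented default parameter set
(100 trees/rounds for the ensembles, depth-3 learners for AdaBoost,
depth-4/16-bin/40-round settings for the oblivious booster) rather than
whatever a library version happens to default to, so orderings are stable
across library upgrades. Ties are broken by ascending gene identifier for
reproducibility.

### MCFS

MCFS grows `s` random feature subsets of size `m`; for each subset it draws
`t` random train/test splits and fits one decision tree per split. The
relative importance of gene $g$ is

$$\mathrm{RI}_g \;=\; \sum_{\tau} (\mathrm{wAcc}_\tau)^u
  \sum_{n_g(\tau)} \mathrm{IG}(n_g(\tau))
  \left(\frac{\mathrm{no.\,in}\,n_g(\tau)}{\mathrm{no.\,in}\,\tau}\right)^v$$

where the inner sum runs over the nodes of tree $\tau$ that split on $g$,
$\mathrm{IG}$ is the split's information gain (bits), the coverage ratio is
the fraction of the tree's training samples reaching the node, and
$\mathrm{wAcc}$ is the tree's class-balanced accuracy (mean per-class
recall) on its held-out split. Genes never sampled score exactly zero.
Defaults are `s = 100`, `m = min(ceiling(0.1 p), 500)`, `t = 5`,
`train_fraction = 0.66`, `u = v = 1`: the original method leaves these
user-set, and this choice keeps a 1,500 × 2,000 run in the one-minute
range while sampling each gene into ~10 subsets on average. Setting
`u = v = 0` collapses the score to summed information gain, which the test
suite exploits as an independently re-walkable oracle.

### Design notes on the boosting rankers

No AdaBoost or oblivious-tree boosting library ships with the package's
dependency set, so both are authored here. AdaBoost is the multiclass SAMME
scheme over depth-3 CART learners with `rpart` case weights; importance is
the $\alpha$-weighted sum of each tree's impurity improvements. Shallow
trees keep the weak-learner condition satisfiable with three classes
(stumps predict at most two classes per round and spread importance over
too few distinct genes to be a useful ranking). The oblivious booster grows
symmetric trees — one shared (feature, bin) split per depth level — on
softmax gradients with Newton leaf values and quantile-histogram bins;
ordered boosting, an overfitting guard of some oblivious-tree
implementations, is deliberately not replicated: at ranking scale the
plain gradient variant orders features identically and is much simpler to
audit.

## Incremental feature selection

`build_subset_sizes(top_n, step)` defines the sweep grid: `step, 2 step,
...` up to `top_n` (appended when not a multiple; clamped to `top_n` when
`step` exceeds it). With the classical settings `top_n = 200, step = 5`
this is the 40-point grid `5, 10, ..., 200`.

`evaluate_subset()` scores one prefix: stratified `cv_folds`-fold
cross-validation (stratification is essential here — with a 15/16.5/68.5
class split, unstratified tenths of a small cohort can lose a class
entirely); within each fold the *training portion only* is SMOTE-balanced,
the classifier is fitted on the balanced set, and the untouched evaluation
fold is predicted. Predictions are pooled across folds — every cell
predicted exactly once — and the pooled vector is scored. Pooling (rather
than averaging per-fold metrics) gives one well-defined confusion matrix
per curve point and is robust to small folds. Synthetic samples can never
leak into an evaluation fold because balancing happens strictly inside the
training portion; whether to balance before or within cross-validation is
genuinely open in descriptions of this design, and the fold-internal choice
is the leakage-safe one.

Two classifiers are swept: CART (Gini, effectively unlimited depth:
`cp = 0, minsplit = 2`) and a 100-tree random forest with $\sqrt{d}$
features per split. On every fixture we generate, the forest dominates the
single tree at each grid point, which the tests assert as a
fixture-specific regression (not a theorem).

## Metrics

With per-class true/false positives and negatives and class weights
$w_i$ = class share of true samples:

$$\mathrm{Precision}_w = \sum_i w_i \mathrm{Precision}_i,\qquad
  \mathrm{Recall}_w = \sum_i w_i \mathrm{Recall}_i,$$
$$\text{weighted }F1 = \frac{2\,\mathrm{Precision}_w\,\mathrm{Recall}_w}
  {\mathrm{Precision}_w + \mathrm{Recall}_w}.$$

Note this is the *harmonic mean of the weighted averages*, *not* the more
common class-share-weighted average of per-class F1 scores; the package
implements the former as `weighted_f1()` (it is the selection criterion
everywhere) and ships the latter as `weighted_f1_classwise()` under an
unambiguous name, because the two genuinely differ on imbalanced
confusions. A class that is never predicted has undefined precision; we
define it as 0 (the standard zero-division convention) so the weighted sum
stays finite, and log the degenerate case.

The multiclass MCC correlates $n \times L$ one-hot indicator matrices of
true and predicted labels: $\mathrm{cov}(X,Y)$ is the sum over the $L$
columns of per-column sample covariances, and
$\mathrm{MCC} = \mathrm{cov}(X,Y)/\sqrt{\mathrm{cov}(X,X)\,\mathrm{cov}(Y,Y)}$
— the $R_K$ matrix-correlation construction, which reduces exactly to the
classical binary MCC at $L = 2$ (the tests verify this exhaustively on
small tables). A constant indicator matrix gives a 0 by convention. How
"covariance of two matrices" should be read is not fully pinned by the
usual verbal definition; the column-summed $R_K$ reading is this package's
recorded choice.

## Essential subsets and consensus

`find_max_point()` returns the smallest prefix size achieving the curve's
maximum weighted F1 (parsimony tie-break; published analyses report unique
maxima and state no rule). When that maximum needs at least
`relative_k_threshold = 100` features, `find_relative_high_point()` looks
for the smallest prefix within `relative_delta = 0.015` of the maximum —
the "relatively high" point that buys a much smaller gene set for a
marginal score drop. The default delta is calibrated to the canonical
worked example of the heuristic (maximum 0.917 at k = 105, relative point
0.903 at k = 50: a gap of 0.014); both knobs are config-exposed since no
numeric criterion is standard. At `delta = 0` the relative point cannot
exist: an earlier exact tie of the maximum would itself be the maximum
point under the parsimony tie-break.

`consensus()` tabulates, for each gene in any essential subset, its
selection count and selecting lists, plus the upset-style cells (genes per
exact list-combination). Essential subsets are taken from the random-forest
curves by default, the stronger of the two classifiers on every fixture
tried; this too is config-overridable.

## Rule extraction

`extract_rules()` SMOTE-balances the *full* dataset restricted to the
essential genes, fits a single CART tree (`cp = 0`, default
`minsplit = 20`, depth capped only by rpart's hard limit of 30), and
renders every root-to-leaf path as a conjunction of `gene <= t` / `gene > t`
predicates predicting the leaf's majority class, with per-class support
counts and purity. A final refit on all data (rather than per-fold trees)
gives one canonical rule set. Same-gene, same-side predicates along a path
are merged to the tightest bound; merging cannot change any sample's
matched rule because intervals only intersect. The rule set partitions
feature space — every input vector matches exactly one rule — which
`apply_rules()` enforces and the tests probe with 10,000 random vectors.
Thresholds are printed at 4 significant digits.

## The synthetic generator

`generate_dataset()` emulates the statistical shape of a log-normalized
scRNA-seq cohort: `L` classes with configurable counts (presets reproduce
the four lung cohorts' active/former/never proportions, e.g. endothelial
6521/7189/29829, largest-remainder-rounded to a configurable total), a
shared nonnegative baseline, Gaussian noise truncated at zero, planted
marker genes with class-dependent additive mean shifts, and independent
Bernoulli dropout. Defaults — 1,500 cells under endothelial-style
imbalance, 2,000 genes, 15 markers (5 per class) shifted by 3 noise SDs,
baseline 2, noise SD 1, dropout 0.3 — are the study conditions for every
ground-truth experiment in the tests and the acceptance script: large
enough that imbalance and sparsity bite, small enough for a desk-scale
run. The generator deliberately does *not* model UMI count distributions,
batch effects, gene–gene correlation, or cell-type hierarchies; passing
recovery tests on it demonstrates that the pipeline's machinery is correct
and sensitive to planted signal, not that it would attain any particular
performance on a real atlas-scale dataset.

## Numerical and reproducibility choices

All randomness derives from one seed through `derive_seed(seed, stage,
index)`, a fixed integer-mixing scheme, so a full pipeline run is
bit-reproducible (the acceptance suite re-runs the whole chain and
byte-compares every artifact). Ranked-list ties break by gene id; `ranger`
and `xgboost` run single-threaded inside the pipeline for determinism.
Degenerate metric inputs (never-predicted classes, constant indicator
matrices) return the logged conventions above rather than NaN. SMOTE
clamps `k_neighbors` to class size − 1 with a warning and refuses
singleton minority classes.

## Problem sizes

The shipped analysis scripts and tests run the study conditions at
1,500 × 2,000 with `top_n = 50` for the IFS sweeps — on this fixture every
curve plateaus above 0.99 weighted F1 well before k = 50, so sweeping to
200 spends minutes re-measuring a flat region. The 40-point `top_n = 200`
grid geometry is exercised separately on a 300 × 200 fixture. Published
atlas-scale analyses (hundreds of thousands of cells, ~28k genes) use the
same code path; only the sizes differ.

## Known limitations

- LASSO importance reflects a single regularization strength chosen by
  internal cross-validation; features zeroed at that strength tie at score
  0 and are ordered by id.
- MCFS constants (`s, m, t, u, v`) follow this package's defaults, not any
  particular historical tool's; rankings are stable under moderate changes
  on planted-marker fixtures, but the exact scores are defaults-dependent.
- Rule counts depend on the tree-growing controls (`minsplit`, depth cap);
  they are reported alongside the controls that produced them.
- The generator's independence assumptions (no gene–gene correlation)
  make ranking easier than on real data; recovery thresholds in the tests
  are calibrated to these conditions only.
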