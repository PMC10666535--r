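---
title: "Meta-learning QSAR models for aquatic toxicity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-learning QSAR models for aquatic toxicity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the data
model and preprocessing rules, the ten learner families, the evaluation
and learning-curve protocols, what the synthetic generator does and does
not emulate, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite does
not itself compute.

## The modelling problem

Each assay is one measurement: species $s$, chemical $c$, exposure
duration $d$ (days) and an LC50 endpoint. We predict
$y = \log_{10}(\mathrm{LC50})$, treating each species as one regression
task. The evaluation contract is *chemicals-disjoint*: the chemical set
is partitioned into $C = C_{\text{train}} \cup C_{\text{test}}$ with
$C_{\text{train}} \cap C_{\text{test}} = \varnothing$, and every assay of
a chemical falls on that chemical's side. A test compound has therefore
never been observed for *any* species during training — the realistic
use case of scoring a newly registered chemical.

Chemicals are described by binary fingerprint bits (1024 by default,
matching hashed circular fingerprints of radius 2), continuous
physico-chemical descriptors (hydrophobicity, i.e. $\log K_{OW}$, chief
among them) and per-column missingness indicators. Duration enters as
$\log_{10}(d)$, since acute (1–4 day) and chronic (21 day and beyond)
tests span orders of magnitude and the transform is otherwise an open
choice. Multi-task families additionally receive one-hot species, class
and phylum encodings.

## Preprocessing

The pipeline order is fixed and each stage can only remove or merge
rows:

1. **Unit standardization** to mg/L via a declared conversion table
   (`default_unit_table()`); rows with unconvertible units (e.g. molar
   units, which would need a molecular weight) are dropped and counted.
   The canonical unit is a package decision — a mass basis keeps the
   table self-contained; a molar variant would only shift per-chemical
   intercepts by $\log_{10} M_w$.
2. **Bound filtering**: endpoints flagged `<`, `>` or "between" reflect
   detection limits, not measured LC50 values; only exact rows survive.
3. **Subspecies merging**: toxicity is modelled at the species level;
   rows recorded below it are folded into the parent species. The
   "empirical mean" is computed on the $\log_{10}$ scale (equivalently a
   geometric mean of raw concentrations) for consistency with replicate
   aggregation — the scale is not dictated by the protocol we mirror, so
   we chose the one that commutes with stage 4.
4. **Replicate aggregation**: repeated (species, chemical, duration)
   measurements collapse to their geometric mean, the REACH-recommended
   aggregate for lognormally distributed test outcomes, so no cell is
   over-represented in training.
5. **Duration normalization** to days; rows lacking a duration are
   dropped.

`build_model_table()` then assembles the numeric design. Feature
decisions are *fitted* on training rows only — median imputation values,
which physchem columns get missingness indicators, which constant
columns are removed, which taxonomy levels exist — and stored in a
schema that is re-applied, never re-fitted, to test rows. "Simple
feature selection" is deliberately minimal: only zero-variance columns
are removed. Rows are canonicalized (sorted by chemical, species,
duration) so that fits are invariant to input row order.

## The learner families

All families obey one contract: `fit_learner(spec, table)` and
`predict(fit, table)` with one real prediction per row; every stochastic
fit is reproducible from `spec$seed`. `can_predict()` reports which rows
a fitted learner can score: per-species families refuse species absent
from training, whereas pooled families fall back on class/phylum
encodings for unseen species (their one-hot species block is simply all
zero).

* **st_mean / mt_mean** — per-species and pooled target means; the
  floors any informative model must beat.
* **st_rf / mt_rf** — CART regression forests (bootstrap + per-node
  feature subsampling, variance-reduction splits), fit per species or
  once on all species with taxonomy features. Implemented in C++ in
  this package with an internal deterministic RNG, because no compiled
  forest dependency is available in the supported environment. Defaults:
  500 trees, unlimited depth, `mtry = p/3`, minimum node size 5. A
  species with fewer than two rows falls back to its mean (logged).
* **mt_stack** — stacked generalization: random-forest,
  gradient-boosted-tree (500 rounds, depth 3, rate 0.05) and RBF-kernel
  support-vector bases combined by a linear meta-learner. The
  meta-regression is trained on out-of-fold base predictions over five
  chemical-level folds to avoid leakage (the source design leaves this
  open; in-sample meta-training would overweight overfit bases).
  Collinear base predictions trigger a small-ridge fallback. The kernel
  base is a least-squares SVR (the LS-SVM linear system) rather than the
  $\varepsilon$-insensitive variant: it is exactly solvable without a QP
  solver and plays the same role in the ensemble.
* **nn_one_output / multitarget_nn** — multilayer perceptrons (two
  rectified hidden layers of 256 units by default, Adam at $10^{-3}$,
  200 epochs, batch 128, early stopping on a 10% chemicals-disjoint
  validation split of the training data). The one-output variant
  consumes taxonomy features; the multitarget variant has one output
  node per training species with the squared loss masked to observed
  (row, species) pairs, and cannot score unseen species (no head
  exists).
* **finetune_top** — the one-output network with every layer except the
  final linear head frozen, and the head retrained per species.
* **maml** — first-order model-agnostic meta-learning of a network
  initialization. The optimizer core is genuinely model-agnostic (it
  needs only a gradient oracle), which is how the test suite verifies it
  against closed-form quadratic-loss updates. First-order rather than
  second-order is the default for stability and cost; divergence aborts
  with a diagnostic rather than returning garbage — the method is known
  to be fragile in this domain.
* **tml / tml_stacked** — transformational machine learning: first-stage
  per-species forests predict each compound, those predictions form the
  compound's representation (dimension = number of first-stage models),
  and second-stage per-species forests learn on the representation. The
  target species' own model *is* included in the representation by
  default (`include_self = FALSE` to exclude it). Second-stage training
  uses in-sample first-stage predictions; an out-of-fold variant was
  considered and deliberately left out — at the per-species data sizes
  this package targets, refitting every first-stage forest per fold
  costs more than the leakage it avoids is worth, and the stacked
  variant (an unweighted mean of the second-stage and the species' own
  first-stage prediction — the aggregation rule is otherwise
  unspecified) already tempers representation overfitting.

A small grid-search harness (`tune_learner()`) over chemicals-disjoint
internal folds stands in for a full hyperparameter-optimization
protocol, which is out of scope.

## Evaluation

RMSE is computed on $\log_{10}$ units, so an RMSE of 1.0 corresponds to
predictions within a multiplicative factor $10^{1.0} = 10$ of the true
concentration. Errors are grouped per species, per chemical or per fold
and summarized by the *unweighted* mean and median over groups; on
unbalanced data the species- and chemical-grouped summaries deliberately
differ, and both are reported. Algorithms are compared with the Friedman
test on per-group ranks (average ranks on ties), the Iman–Davenport
correction, and Nemenyi critical differences
$CD = q_\alpha \sqrt{k(k+1)/(6N)}$; $q_\alpha$ is computed as
$q_{\text{tukey}}(1-\alpha, k, \infty)/\sqrt{2}$, which reproduces the
published table values (the tests check $k=3$, $\alpha=0.05$ to the
printed precision).

The internal stability protocol partitions training chemicals into five
disjoint, equally sized subfolds, repeated over three partitions — 15
estimates per learner. A leakage audit is instrumented in the fit
harness itself: every training table is asserted free of test chemicals
*before* any fit, imputation or feature-selection step, and a violation
is an error, not a warning.

## Learning-curve experiments

**Assays per species (R2).** After a 90/10 chemical split, species with
at least 128 training assays become *study species*; the others' training
rows form an *auxiliary set* and their test rows are discarded, fixing
the test set for the whole experiment. At anchor $s$, single-task
learners see $s$ rows of the target species and multi-task learners see
$s$ rows from every study species (plus the full auxiliary set in the
with-auxiliary arm). Sampling is nested — rows used at an anchor are
reused at all larger anchors within an ordering — and three orderings
are averaged. The default anchor schedule is the $\sqrt{2}$-spaced fill
`{5, 8, 11, 16, 22, 32, 45, 64, 90, 128}`.

**Auxiliary species count (R3).** After a 75/25 split, species with at
least three distinct test chemicals are study species; remaining species
with at least 64 training assays are auxiliary species, down-sampled to
exactly 64 rows so that curve movement is attributable to added *species*
rather than added rows. For each study species and count $n$, multi-task
learners train on the study species' rows plus the first $n$ auxiliary
species of a per-seed permutation (a prefix, so count $n$ is contained in
count $n+1$); three seeds are averaged and single-task learners are
excluded. The default count grid is `{0, 2, 4, 8, 16, 32, 64}`; the
protocol we mirror states both this doubling grid and a linear
`1..12` grid in different places, so the grid is an argument rather than
a constant.

Curve points carry 90% percentile bootstrap bands over 1000 resamples of
the *group-level* RMSEs (species or chemicals — the aggregation unit —
not raw residuals).

## The synthetic generator: what a green test establishes

The generator states a world with known ground truth:

$$y = \alpha_s + w_s \cdot \log K_{OW} + \beta_d \log_{10}(d) + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2)$$

* $\alpha_s$ decomposes exactly into phylum + class + species Gaussian
  draws (scales 0.5 / 0.3 / 0.3 log units), so taxonomy carries real
  signal and the multi-task advantage is a *property of the world*, not
  an artifact.
* $w_s \sim N(-0.85, 0.15^2)$: the classic baseline-narcosis slope on
  hydrophobicity, mildly species-varying.
* $\beta_d = -0.3$: toxicity increases (LC50 drops) with exposure time.
* $\sigma = 0.5$ log units: typical inter-laboratory variability.
* Assay counts per species follow a truncated Zipf law (exponent 1.2 at
  full scale) renormalized to a configured total — one parameter for the
  heavy tail.
* A 10% fraction of cells receives 2–4 replicates with multiplicative
  lognormal noise (0.1 log units) on the raw scale, so the geometric
  mean is the *correct* aggregator by construction; 5% of rows are
  flagged `<`/`>` at the species' 5th/95th raw percentile, mimicking
  detection limits.
* Durations are drawn from `{1, 2, 4, 21}` days — the standard
  acute/chronic test lengths; the real duration distribution is not
  published, so this is a package choice.
* Full-scale defaults (9 phyla, ~20 classes, 351 species, 2674
  chemicals, 24816 assays, 1024 fingerprint bits) mirror the collection
  the package is designed around; tests run smaller instances of the
  same family, which changes compute, not the distributional statement.

What the generator does **not** emulate: real fingerprint bit
correlations (bits are independent Bernoulli with Beta-distributed
activation rates), chemical-class clustering, mode-of-action switches
away from narcosis, species-by-chemical interaction structure beyond the
additive surface, and real-data label noise heterogeneity. A green
multi-task-advantage test therefore establishes that the implementations
exploit taxonomy-correlated task relatedness when it exists — not that
any particular advantage holds on a given real collection.

## Numerical choices and degenerate inputs

* Forests, boosting and the networks use internal, explicitly seeded
  RNGs; fits are bit-reproducible and independent of R's global RNG
  state (generator and sampling code use scoped seeds via `withr`).
* Split search requires a strict variance improvement ($>10^{-12}$);
  pure or sub-minimal nodes become leaves.
* The LS-SVR solves one dense linear system; it is cubic in $n$ and
  intended for the moderate table sizes of the stacking ensemble.
* Friedman with all-tied rows returns statistic 0 and $p = 1$; a
  saturated statistic returns $F_F = \infty$, $p = 0$.
* Bootstrap bands from a single group degenerate to the point estimate
  with a warning.
* Zipf counts use largest-remainder rounding with a floor of one assay
  per species, so counts are non-increasing in rank and sum exactly to
  the configured total.
* All-missing physchem training columns impute to 0 after the median is
  undefined; missingness first seen at prediction time imputes to the
  training median without creating new indicator columns.

## Known limitations

* No applicability-domain estimation (deliberately out of scope).
* No structure-based featurization: synthetic chemicals are feature
  vectors; plugging in real fingerprints is a data question, not a code
  change.
* MAML is implemented first-order only; the second-order variant is a
  documented non-goal.
* The acceptance criteria that involve forests run at reduced scale
  (100 trees, 128 fingerprint bits) to stay within desk-scale compute
  budgets; the generator's distributional parameters are untouched.
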