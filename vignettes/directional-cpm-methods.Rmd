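---
title: "Directional connectome-based predictive modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional connectome-based predictive modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Case-control studies of resting-state functional connectivity (rsFC)
disagree about the *direction* of connectivity alterations in schizophrenia:
some report only decreased connectivity in patients, others both decreased
and increased. `conncpm` implements a multivariate way to ask whether
increased connectivity carries information over and above decreased
connectivity: build classifiers from edges increased in patients, from edges
decreased in patients, and from both, and compare their cross-validated
accuracy. If adding the increased-edge score improves prediction, increased
connectivity adds information about the diagnosis.

# The model

Each subject is represented by the strict upper triangle of a symmetric
$n \times n$ Fisher-z connectivity matrix ("edges"; $E = n(n-1)/2$). The
classifier is a modified connectome-based predictive model (CPM):

1. **Edge-wise selection.** Every edge is Pearson-correlated with the binary
   diagnosis label (patient = 1, control = 0). For a binary variable this is
   the point-biserial correlation, and the two-sided p-value from
   $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df is *identical* to an
   equal-variance two-sample t-test comparing the groups on that edge; the
   test suite asserts this identity to $10^{-10}$.
2. **Sign split.** Edges with $p < \theta$ are split by the sign of $r$ into
   an *increased* set ($r > 0$: higher in patients) and a *decreased* set
   ($r < 0$).
3. **Summation.** Each set is summed per subject into a single score,
   reducing $E$ dimensions to one or two predictive variables.
4. **Classification.** A soft-margin linear classifier (hinge loss, box
   constraint $C = 1$, no feature standardization) is fit on the 1- or
   2-dimensional score space. Three modes are compared: `increased`,
   `decreased`, and `both`.

Validation never lets selection see held-out data: leave-one-out and
stratified k-fold cross-validation refit the entire pipeline (selection
included) inside every fold. Significance uses (a) a label-permutation test
that reruns the full pipeline per shuffle, with the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, and (b) an exact
one-sided sign test of per-subject correctness against chance 0.5. For
interpretation, edges selected in at least 90% of folds ("consensus edges")
are aggregated into network-pair counts over the ten canonical networks
(CBL, SC, SAL, VAs, VI, VII, Mot, DMN, FP, MF).

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.05 | selection p-threshold; `threshold_search()` scans 0.05, 0.01, 0.005, 0.001 and returns the LOOCV-best (ties to the smallest) |
| `C` | 1 | box constraint of the linear classifier |
| `k` | 10 | folds for `kfold_cv()` (stratified by class) |
| `B` | 1000 | label shuffles in `permutation_test()` |
| `fraction` | 0.9 | consensus-edge fold fraction (inclusive: 90 of 100 folds qualifies) |

Because the threshold search criterion is LOOCV accuracy on the same
dataset, the best-threshold accuracy is optimistically biased; the full
per-threshold table is always returned and reported so this is visible, and
no correction is applied (the procedure is reported as run).

# Design choices in ambiguous corners

* **Two-sided selection p-values.** Selection could be one- or two-sided;
  two-sided is the conventional reading and keeps the sign split meaningful.
  The split itself is the directional step.
* **Ties at the decision boundary** (decision value exactly 0) predict
  class 1. Some fixed rule is required for determinism; the direction is
  arbitrary and documented.
* **Constant edges** get $r = 0$, $p = 1$ and are never selected: an
  undefined correlation must not enter a mask.
* **Empty selection.** If no edge survives the threshold for a mode, the
  model predicts the majority training class (ties toward control) and a
  warning is raised; cross-validation aggregates these warnings per run.
* **Diagonal and edge order.** Self-connectivity is excluded (stored
  diagonal 0; $\mathrm{atanh}(1)$ is undefined). Edge vectors use the strict
  upper triangle in row-major order — pairs $(i, j)$, $i < j$, 0-based —
  and this order is the contract for every mask, edge list, and serialized
  model.
* **Symmetry tolerance.** User-supplied matrices are accepted if
  $\max|M - M^\top| \le 10^{-12}$ and symmetrized as $(M + M^\top)/2$,
  otherwise rejected. A reader flag declares whether inputs store raw
  Pearson r (transformed on load) or Fisher z; there is no default because
  deposits differ and guessing silently corrupts scale.
* **Permutation scheme.** Shuffles are applied to the cohort labels before
  the evaluator runs, so LOOCV/k-fold permutations re-select features in
  every fold under the null; for cross-dataset evaluation the *training*
  labels are shuffled and the test cohort stays fixed. Degenerate shuffles
  (single-class folds) are redrawn with a message.
* **Classifier implementation.** The 1–2 dimensional linear SVM is solved
  by libsvm. The package calls libsvm's registered training routine
  directly and extracts the explicit rule $(w, b)$, oriented so positive
  decision values mean class 1; the test suite pins this path to
  `e1071::svm()` decision values on randomized problems. This keeps
  permutation nulls (hundreds of thousands of refits) fast without changing
  the fitted model.
* **Cross-validation arithmetic.** Per-fold training sums are computed as
  crossproducts with a 0/1 training-indicator vector, so held-out rows
  enter the fitted model only as $x \cdot 0$: the no-leakage guarantee
  holds bit-for-bit, and the tests assert it by perturbing held-out
  subjects.
* **Seeding.** Every stochastic operation takes one integer seed and
  restores the caller's RNG state. Operations that need several seed
  streams (e.g. permutation fold assignments) draw child seeds from the
  seeded stream in a fixed order, so one top-level seed reproduces
  everything bit-for-bit.

# The synthetic-data generator

`generate_cohort()` plants effects directly in Fisher-z edge space: edge
baselines are drawn once per cohort from
$\mathcal{N}(\mu_0 = 0.3, \sigma_0 = 0.2)$, each subject adds i.i.d.
$\mathcal{N}(0, \sigma = 0.2)$ noise per edge, and patients are shifted by
$+\delta$ on planted increased edges and $-\delta$ on planted decreased
edges. The default $\delta = 0.2$ equals one subject-noise sd — a moderate
univariate effect that leaves single-edge tests underpowered at small n,
which is the regime the summed-score approach is designed for. The z-space
defaults sit in the range typical of Fisher-transformed resting-state
correlations; planting in z-space gives exact control of per-edge effect
size. The default test scale is 60 nodes (1,770 edges); the full 268-node
scale (35,778 edges) is available by argument.

`generate_two_sites()` encodes the multi-site structure the analysis is
designed to probe: a decreased edge set shared by both sites, per-site
increased edge sets with a controllable overlap fraction, and independent
per-site baselines (a site effect). With overlap 0, decreased-edge models
should transfer between sites and increased-edge models should not.

`generate_timeseries_cohort()` is the slow end-to-end path: subject-level
target z-edges are mapped to correlations by $\tanh$, repaired to the
nearest valid correlation matrix (eigenvalue clipping at $10^{-6}$, then
renormalization to unit diagonal), and used as the population correlation
of multivariate-normal node time series, so `compute_fc()` recovers the
planted structure as the series lengthens.

What the generator does *not* emulate: hemodynamic autocorrelation, motion
artifacts, non-Gaussian tails, spatially structured covariance among edges,
or scanner effects beyond the site-level baseline shift. Passing tests on
this generator therefore demonstrate correctness of the statistical
machinery and recoverability of planted structure, not performance on real
fMRI data.

# Validation at study scale

The acceptance tests run the pipeline at deliberately chosen problem sizes:
selection calibration on 100 null cohorts (60 subjects, 1,770 edges);
LOOCV-accuracy and permutation-p calibration on 200 null cohorts with
$B = 200$ shuffles each (the permutation evaluator there is stratified
10-fold CV, the cheaper of the two validated evaluators, keeping roughly
400,000 pipeline refits tractable); the bidirectional-gain comparison on
100 cohorts of 100 subjects with 30 + 30 planted edges at $\delta = 1\sigma$;
and the transfer-asymmetry comparison on 100 two-site replicates. Null
calibration checks use exact binomial intervals around the nominal rates.

# Known limitations

* The sign split assumes a homogeneous direction per edge across patients;
  mixtures within an edge dilute both scores.
* Summation weights every selected edge equally; no within-set weighting is
  attempted (by design, for interpretability).
* The permutation p-value is bounded below by $1/(B+1)$.
* Threshold search is not nested inside cross-validation, so its winning
  accuracy is optimistic (reported, not corrected).
* Network-pair counts depend on the atlas's network assignment; with the
  synthetic block atlas they describe recovery bookkeeping, not anatomy.
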