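---
title: "Virtual re-hybridization: simulating handling effects to benchmark normalization and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual re-hybridization: simulating handling effects to benchmark normalization and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A paired microarray study profiles the same samples twice: once with
uniform handling (one technician, one batch, balanced assignment) and
once with the arrays processed over time in collection order. Writing
`x^{u}_j` for sample `j`'s uniformly handled profile and `x^{n}_{a(j)}`
for its profile on array `a(j)` of the non-uniform dataset (both on the
log2 scale), the package adopts the additive decomposition

* biological effect of sample `j` ("virtual sample"): `b_j = x^{u}_j`;
* handling effect of array `a` ("virtual array"):
  `h_a = x^{n}_a − x^{u}_{j(a)}`.

The decomposition is lossless by construction — `b_j + h_{a(j)}`
reconstructs the non-uniform data exactly — and it makes no modeling
assumptions: the handling estimator is the raw paired difference, not a
regression or smoothing fit. Its cost is that `h_a` absorbs everything
that differs between the two hybridizations of a sample, including
biological noise; for benchmarking purposes that is a feature, since the
simulated data inherit the full empirical artifact distribution.

**Virtual re-hybridization** simulates a dataset under a chosen
array-to-sample assignment by re-summing `x_j = b_j + h_{a(j)}`. Because
the assignment is under the analyst's control, so is the confounding
structure:

* `confounding` — arrays in ascending processing order go to one class
  first, then the other, aligning class perfectly with processing order
  (the rank-sum of one class's processing orders is minimal over all
  bijections);
* `balanced` — arrays are cut into consecutive processing-order blocks,
  each receiving an equal number of samples from each class, randomized
  within the block (blocking + randomization + stratification);
* `complete_random` — a uniformly random bijection.

Two dials set the signal-to-noise regime. `reduce_signal(bio, f)` moves
each value toward the midpoint of the two class means,
`x′ = x − (1−f)(m_{c(j)} − m̄)`, so every per-probe class-mean difference
is scaled by `f` while within-class deviations are untouched; the
operation composes multiplicatively (`f1` then `f2` equals `f1·f2`).
`amplify_handling_effects(handling, f)` multiplies selected virtual-array
columns elementwise by `f ≥ 0`, with no re-centering.

## Study structure and splits

At the original scale, 96 + 96 samples are profiled twice, giving 192
virtual samples and 192 virtual arrays. Per simulation repetition the
samples are split randomly 2:1 (stratified by class) into training and
test sets, while the arrays are split deterministically by processing
order: first and last thirds to training, middle third to test (64/64/64
at scale). The generalization to arbitrary sizes is exact thirds,
requiring divisibility by 3 and failing loudly otherwise. Test-set
profiles with biological effects only (no handling added) form the
**benchmark** test data — the yardstick: a classifier's error there
measures what it learned about biology rather than about handling.

## Preprocessing and normalization

Preprocessing is fixed as: load raw intensities → log2 transform →
normalization → probe-replicate summarization by the median (even-sized
replicate sets use the midpoint of the central order statistics;
replicate rows are matched by string-equal probe IDs after whitespace
trimming). The log2 step precedes effect estimation; the package guards
against double transformation via a scale flag.

Training normalization (`normalize_train`) freezes a reference:

* **median** — each array is shifted so its median equals the median of
  per-array medians; that scalar is the frozen reference.
* **quantile** — each array's sorted values are replaced by the
  across-array mean of order statistics; that vector is the frozen
  reference. Ties share the mean of the reference values at their tied
  ranks, so tied inputs stay tied and the map is monotone.
* **vsn** (simplified) — per-array affine calibration against the mean
  order statistics of the raw intensities, inside
  `asinh(·/s0)/log(2)`, with the glog scale `s0` chosen by
  one-dimensional optimization to flatten the per-probe spread across
  five intensity strata. This is deliberately a two-parameter-per-array
  calibration plus one global scale — the contract tested is
  monotonicity and variance flattening, not coefficient equality with
  full robust maximum-likelihood VSN, which is out of scope.

The seven test-data strategies are the three methods applied to the test
set **alone**, the three **frozen** toward the training reference (each
test array mapped one at a time; frozen strategies never read other test
arrays, so subset and permutation invariance holds by construction), and
**pooled quantile** normalization (train + test concatenated, quantile
normalized jointly, test columns returned). "No normalization" is kept
as a reference entry outside the count of seven. In the assessment grid,
a frozen strategy paired with a non-matching training normalization has
no defined reference; such cells are retained with an explicit
`incompatible` status rather than silently dropped, keeping the grid
complete. An optional location-only batch correction (per probe and
batch, subtract the batch mean, add back the grand mean) is available
and off by default; no specific published batch method is claimed.

## Classifiers and validation

PAM (nearest shrunken centroids), DLDA, and ClaNC are implemented in the
package; lasso-penalized logistic regression, kNN, random forest, and
linear SVM delegate their core fits to `glmnet`, `class`,
`randomForest`, and `e1071`. Conventions that matter for
reproducibility:

* PAM: `d_{kg} = (x̄_{kg} − x̄_g)/(m_k (s_g + s_0))` with
  `m_k = sqrt(1/n_k − 1/n)` and `s_0` the median pooled SD; the
  threshold is chosen from 30 values spanning 0 to `max |d|` by seeded
  stratified cross-validation, ties to the smallest threshold. At
  threshold 0 the rule is exactly a standardized nearest centroid with
  class priors.
* ClaNC selects probes per class by the unshrunken `|d|` statistic,
  greedily and without overlap while unclaimed probes remain; between
  classes tied on `|d|` for the same probe (always, for two equal-sized
  classes) the up-regulated class wins, making selection invariant to
  relabeling. A class that cannot fill its quota (requests exceeding
  half the probes) completes it from its own ranked list, so at
  `genes_per_class = n_probes` every probe is active for every class and
  the rule degrades to the plain standardized nearest centroid.
* Default grids: lasso uses glmnet's 50-step path (ties to the largest
  penalty); kNN k ∈ {1,3,5,7,9,11} (ties to the largest k); RF 500
  trees; SVM linear kernel, cost ∈ {0.01,0.1,1,10} (ties to the
  smallest cost), no feature rescaling. Default folds: 5, stratified.
  Prediction score ties break to the first class label in sort order.
* Every stochastic step takes an explicit integer seed; repetition `r`
  of a pipeline run derives its seeds as `base_seed + r` plus fixed
  offsets, and per-classifier seeds are indexed by registry position so
  a single-classifier run reproduces the corresponding cells of a joint
  run bit for bit.

Validation targets are three, not two: cross-validation on the training
set, external validation on the simulated (handling-affected) test set,
and external validation on the handling-free benchmark. The benchmark
is the accuracy yardstick; the simulated external set shows what an
analyst would observe in practice. All three report the
misclassification proportion, exactly `(# misclassified)/(# tested)`.

## The synthetic generator

`generate_paired_study(fixture_spec(...))` emulates the paired structure
with additive log2-scale layers: per-probe baselines uniform on 6–10
log2 units; a class effect `δ` on an informative probe subset; Gaussian
noise at row level (replicate noise shares `bio_sd`, since separating
the two scales adds a parameter the downstream contracts never see); a
handling layer equal to a monotone logistic ramp over processing order
spanning `trend_amplitude` (per-row loadings uniform on 0.5–1.5, so the
trend is probe-dependent as on real arrays) plus contiguous batch
offsets plus Gaussian noise. Matrices are exponentiated to the raw
intensity scale so the full load → log2 → decomposition path is
exercised; ground truth is stored log2-scale in a side-channel attribute
that pipeline stages never read. The deterministic monotone trend is
what lets a confounded design provably transfer class-correlated
structure — the phenomenon the framework exists to expose.

The desk-scale default (24 samples per class, 120 probes in triplicate,
24 informative, δ = 1.5, `bio_sd` 0.5, trend 1.0, batches ±0.5,
`handling_sd` 0.3) keeps every test and the full assessment grid fast
while remaining comfortably separable (DLDA external error below 0.1
across seeds). What passing tests on it shows — and does not show:
the generator has Gaussian noise, a smooth trend, and exact additivity,
whereas real arrays have heavy-tailed artifacts, spatial effects, and
probe-specific handling responses. Results here validate the
machinery's contracts, not any claim about which normalization wins on
real data.

## Numerical choices and degenerate inputs

* "Exact" reconstruction assertions tolerate 1e-12 for the
  `2^x`/`log2` round trip; the frozen-quantile map is bit-exact for
  untied values.
* Raw intensities must be strictly positive and complete; missing values
  are rejected at load rather than imputed.
* Zero-variance probes are excluded from DLDA with a warning; an
  all-zero-variance matrix is an error. PAM thresholds above every
  `|d|` shrink all probes out and fall back to class priors.
* The balanced design's default block size is `2·ceiling(n/48)` — 8 at
  the 192-array scale, scaling down proportionally — always even, and
  must divide the array count.
* Failed grid cells carry an explicit `error` status; the grid is never
  silently incomplete.

## A known regime worth understanding

With a strong handling trend (e.g. amplitude 2) and *no* normalization,
training arrays are globally brighter than the handling-free benchmark,
so any location-sensitive classifier predicts a single class externally
and both confounded and balanced designs sit at the coin-flip error of
0.5. The design effect (confounded ≥ balanced) then holds as an
equality at saturation; the contrast between designs re-emerges as soon
as any location-correcting normalization enters the grid, which is the
package's central demonstration (see the README's worked example).

## Default problem sizes

The test suite and the acceptance script run the desk-scale fixture
throughout, with a 96-per-class (192-sample) study generated at reduced
probe count for the structural checks and 20 repetitions for the
design-effect comparison — sizes chosen so a complete run exercises
every code path in well under a minute of simulation per check.
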