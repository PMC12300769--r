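---
title: "Methods: stratified augmentation, composite feature scoring and equation discovery for log RCF modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified augmentation, composite feature scoring and equation discovery for log RCF modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

The root concentration factor (RCF) — the ratio of a contaminant's
concentration in plant roots to its concentration in the exposure medium —
summarizes how strongly a compound accumulates in root tissue. For per- and
polyfluoroalkyl substances (PFASs) in hydroponic systems, experimental RCF
measurements are scarce: a few hundred literature records covering many
compounds, species and exposure regimes. Two obstacles follow. First,
sample sizes are too small for flexible learners to be trained reliably.
Second, even a well-fitting gradient-boosted model is opaque; risk
assessment wants an explicit equation in molecular descriptors.

`sdml` implements a workflow that addresses both: regression-aware data
augmentation to enlarge small training sets while preserving the target
distribution, boosted-tree models with Bayesian hyperparameter search and
Shapley-value explanation, and three symbolic-regression engines that emit
evaluable, serializable equations for log10 RCF.

## Data model and preprocessing

All stages exchange a `feature_table`: a data frame of chemical-exposure
records (molecular weight in g/mol, log Kow, pKa, TPSA in Å², exposure time,
an integer-coded plant species, ...) with a designated target column
(`logRCF`, dimensionless, log10 scale). Missing cells are `NA` — R's native
sentinel, distinct from every legal value.

Preprocessing runs in a fixed order; each stage reports what it changed.

1. **Imputation.** Round-robin random-forest regression: each incomplete
   column is regressed on all others and its missing entries replaced,
   cycling until the largest change falls below 10⁻³ of the column scale or
   10 rounds. 100 trees per forest; categorical columns are imputed by
   nearest observed code.
2. **Outlier trimming.** Rows whose *target* lies outside
   [Q1 − 1.5·IQR, Q3 + 1.5·IQR] are removed. Quartiles use linear (type-7)
   interpolation, stated explicitly because the trimmed set depends on it.
   Only the target is trimmed — descriptor outliers are left to the tree
   models, which are insensitive to monotone feature distortions. Trimming
   is applied once; reapplying it after removals can remove more rows
   (the quartiles move), which is why the pipeline order is fixed.
3. **Symmetrization.** Continuous columns with adjusted Fisher–Pearson
   skewness above 1 are replaced by `log10(x + shift)`,
   `shift = max(0, 10⁻⁶ − min(x))`; base 10 because RCF-type quantities are
   conventionally reported on that scale.
4. **Encoding.** Categorical labels become 0-based integer codes in order
   of first appearance; tree models split on the codes directly.

## Composite feature scoring

Single dependence statistics each miss something: the F-statistic sees only
linear trends, mutual information is scale-free but noisy at small n,
distance correlation detects general dependence but not local structure.
The scoring operation therefore combines five statistics — univariate
F-statistic, Kraskov k-nearest-neighbour mutual information (k = 3),
distance correlation, an equi-partition approximation of the maximal
information coefficient (grid budget n^0.6), and RReliefF (10 neighbours) —
each min–max normalized across features and combined with equal weights
(0.2 each; nothing in the method fixes other weights, and equal weighting
avoids privileging any dependence type). The combined score is multiplied by

* a **stability factor**: the fraction of 100 bootstrap resamples (80%
  size) in which the feature ranks in the top half of the combined score;
  features whose apparent relevance is a sampling artefact are discounted;
* a **collinearity penalty** `1 / (1 + max(0, VIF − 10) / 10)`, with the
  variance inflation factor computed against all other features; 10 is the
  classical multicollinearity threshold. An exactly duplicated feature has
  infinite VIF and a composite of 0.

The composite therefore stays in [0, 1] and is, by construction, invariant
to affine rescaling of any single feature. Derived features append two
domain composites — a water-solubility index
`TPSA / (MW · (1 + 0.5 · log Kow))` and saturating absorption kinetics
`1 − exp(−0.005 · t)` — plus generic squares, square roots, protected logs
and pairwise products of the five base descriptors.

## Stratified dual-pipeline augmentation

The augmentation operation is the package's core. The training target is
split into `max(6, min(12, floor(n_train / 12)))` bins — equal-frequency
when |skewness| > 1 (so sparse tails still get populated bins), equal-width
otherwise (preserving the physical meaning of RCF intervals). The synthetic
budget `round((f − 1) · n_train)` for expansion factor `f` (default 9:
the training set grows nine-fold) is apportioned over bins proportionally
to each bin's deficit toward the largest bin, by largest remainder — sparse
target regions receive the most synthetic mass, which is what rebalances a
peaked log RCF marginal.

Two generators fill the quotas, half each by default:

* **SMOTER** interpolates between a seed row and one of its 5 nearest
  in-bin neighbours: `x_new = x_i + μ(x_nn − x_i) + δ`, `μ ~ U(0,1)`, with
  per-feature Gaussian noise `δ_f ~ N(0, (0.02 · sd_f)²)`; the target
  interpolates with the same μ and no noise, so synthetic targets stay in
  their bin. Neighbourhoods use the standardized Euclidean metric over
  continuous features **plus a large penalty per mismatching categorical
  code**. The penalty matters: rows from different plant species can share
  a target bin while sitting on offset response surfaces, and interpolating
  across them manufactures records whose target mixes two species' levels
  while carrying one species' code. Restricting partners to the seed's
  categorical profile (falling back only when a bin has no such partner)
  keeps category-conditional relationships intact.
* A **variational autoencoder** — tanh MLP encoder/decoder (hidden layers
  32 and 16, 8 latent units) trained for 200 epochs (batch 32, Adam,
  learning rate 10⁻³) on the standardized features-plus-target — captures
  joint nonlinear structure that pairwise interpolation cannot. Sampling
  the latent prior and decoding yields complete records; categorical codes
  are snapped to the nearest observed value and decoded targets outside
  the observed range (±5%) are redrawn.

Every candidate passes **quality control** before it counts against a
quota: all continuous features inside the assigned bin's observed envelope
widened by 5% of the bin range, and the target inside the bin edges ±10%
of the bin width. Rounds repeat (at most 20) until quotas are met; in the
last two rounds SMOTER covers any remainder in donor-bearing bins, and an
unreachable quota degrades to a warning and partial augmentation, never an
error. Every random draw (seed row, neighbour, μ, δ, latent z) is logged so
generation can be replayed exactly — the test suite verifies synthetic rows
coordinate-wise against the logged draws.

## Models, tuning and explanation

Four tree ensembles are trained: three gradient-boosting variants (named
`catboost_like`, `lightgbm_like` — leaf-wise growth with a conditional dart
branch — and `xgboost_like`, all realized as distinct search spaces over
the xgboost engine) and a ranger random forest. The harness, search spaces
and evaluation protocol are the package's contribution; re-deriving
boosting internals is not.

Hyperparameters are tuned by a tree-structured Parzen estimator:
learning rates log-uniform in [10⁻³, 0.3] (they act multiplicatively),
subsampling rates uniform in [0.5, 1], integer depth/leaf ranges, and
conditional parameters (dart's `rate_drop`) sampled only when their branch
is active. The objective is mean 5-fold cross-validated RMSE on folds fixed
per run; the incumbent is refit on the full training set and the test set
is scored exactly once per report. Augmentation is applied to training data
only — the test set never contains synthetic rows.

Explanation is tiered, recording which tier ran: the engine's native exact
contributions where available; otherwise exact Shapley values of the
cover-weighted conditional-expectation game on the extracted trees
(enumerating subsets of the ≤ 14 features the ensemble actually uses —
additivity to machine precision, unused features exactly zero); otherwise
the kernel approximation with a k-means (k = 10) background. Per-model
importance is mean |SHAP| normalized to sum 1, aggregated across models by
mean rank.

## Equation discovery

Three engines emit `equation` objects — linear combinations of
product-of-factor terms (or a full expression tree for GP) with protected
operators throughout, JSON-serializable and closed under
serialize → parse → evaluate.

* **GP**: tournament-selected genetic programming over
  {+, −, ×, protected ÷, protected log, √|·|, sin, abs, protected power},
  fitness RMSE + 0.001 · size, population 2000 for 100 generations by
  default (crossover 0.7, mutation 0.2, tournament 20).
* **MFTEC** (select-then-construct): top-m features by composite score
  (m = 8), then three dictionary blocks (linear, pairwise interactions,
  transforms including `exp(−0.005 t)` for time-like features), each fit
  with an elastic net, stacked by non-negative least squares on the block
  predictions, and flattened exactly into one equation (the flattening is
  algebraic, so flattened and pipeline predictions agree to 10⁻⁸).
* **HSIE** (construct-then-select): the full dictionary of monomials to
  order 3 plus square roots, protected logs and pairwise protected ratios
  (capped at 20 000 columns), L1-penalized with the penalty chosen by
  5-fold cross-validation (the sparser `lambda.1se` rule), then refit
  unpenalized on the support so coefficients are on the natural scale, and
  pruned of numerically negligible terms. With `max_order = 1` the
  dictionary is exactly the raw features and the result coincides with
  ordinary least squares.

## The synthetic generator and what passing tests mean

The study dataset is not public, so every stage is validated against a
generator with known ground truth: MW ~ U(214, 714) g/mol (short- to
long-chain PFAS masses; a plausibility choice carrying no chemical claim),
log Kow coupled to MW, pKa ~ U(−1, 5), TPSA ~ U(0, 80) Å², exposure time
~ U(1, 60) d, and a species code with offsets spanning 3 log units. The
response is `b₁·MW/100 + b₂·(1 − e^(−0.005t)) − b₃·WSI + species offset +
b₄·(MW/100)(1 − e^(−0.005t)) + ε`, betas (1.0, 0.8, 1.2, 0.5).

Two generator conditions deserve explanation:

* **Noise calibration.** With these ranges and betas the noiseless response
  has variance 3.41; `noise_sd = 0.78` is fixed analytically so the
  achievable R² is ≈ 0.85, matching the regime of published log RCF models.
  It is derived from the ceiling condition, not fitted to any test.
* **Species occupancy.** Real log RCF compilations are concentrated — a
  dominant central mode with sparse tails — and that imbalance is precisely
  what quota-based augmentation targets. Species are therefore sampled with
  Gaussian occupancy (≈ 0.2/0.6/0.2), not uniformly.

What the generator does *not* emulate: literature heterogeneity (multiple
labs, protocols, measurement error structure), correlated descriptor noise,
and compound-family clustering. Passing tests therefore demonstrate that
the machinery is implemented correctly and behaves as designed on clean
tabular data with known structure — not that augmentation will improve any
particular real dataset.

Two honest negative results from this validation are worth recording.
First, on this clean generator the boosting models' mean test R² is not
improved by nine-fold augmentation (deltas of roughly −0.01 over 20
replicates at n_train = 150): interpolated and VAE rows add no information
beyond the original draws, and the gains reported on literature-compiled
data do not reproduce here. Second, the select-then-construct and sparse
high-order engines are statistically tied on this generator (means within
0.001): the planted truth contains no third-order structure, so the richer
dictionary — the reason the high-order engine wins on real data — has
nothing to exploit. The corresponding directional test encodes both
expectations and is expected to fail on this generator; it is retained
unweakened as documentation of the gap between the clean synthetic regime
and heterogeneous real data.

## Numerical choices and degenerate inputs

* Half-up rounding for the train split size; floor for the bin-count
  formula (bounds make the choice inert near 6 and 12).
* Equal-frequency bin edges fall back to equal width when target ties
  produce duplicate quantile edges.
* Protected operators use an ε-floor of 10⁻⁶ (`log(|x| + ε)`,
  `1/(|x| + ε)`, division guarded at |denominator| > 10⁻⁶).
* Quota apportionment breaks remainder ties toward lower bins; top-k
  feature selection breaks composite ties lexicographically.
* Constant features score a composite of 0 and are flagged; constant
  targets collapse the equation engines to an intercept; a zero-variance
  test target makes R² undefined and is reported as `NA` with a warning.
* Single-donor bins cannot seed SMOTER; their quota routes to the VAE
  pipeline, and if the VAE is disabled, to the nearest populated bin.
* The Kraskov estimator clamps neighbour counts when bootstrap duplicates
  collapse distances to zero.
* All engines run single-threaded with explicit seeds; identical inputs
  and seeds give byte-identical outputs (xgboost stores models in single
  precision, so its additivity checks hold to ~10⁻⁶ rather than 10⁻¹⁵).

## Problem sizes used in validation

The shipped validation suite runs the full augmentation at the study scale
(462 training rows, expansion 9 → 4158 rows), feature-recovery over 50
seeds at n = 150 with 20 candidate features, sparse-interaction recovery
over 20 seeds at n = 500, and the directional benchmarks over 20 seeds at
n = 616 with 75/25 splits; the genetic-programming engine runs at a reduced
budget (population 200, 10 generations) in the comparative benchmark, with
its full default budget (2000 × 100) exercised only on its own recovery
task. These sizes were chosen so the whole suite completes on a laptop-class
single core.

## Known limitations

* VAE sample quality at a few hundred training rows is modest; its
  acceptance rate through quality control is well below SMOTER's, and the
  loop compensates by routing the remainder to SMOTER.
* Exact support identification by the sparse engines is impossible when
  the dictionary contains nearly collinear columns (over a positive bounded
  range, MW, √MW and MW² are almost affine images of each other); the
  engines recover the response function, not a unique basis for it.
* The TPE implementation models parameters with independent
  one-dimensional Parzen densities; parameter interactions guide the
  search only through the shared good/bad split.
* No GAN or diffusion generators; no multivariate outlier detection; no
  descriptor computation from structures (the workflow consumes a prebuilt
  feature table; an adapter seam is left open).
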