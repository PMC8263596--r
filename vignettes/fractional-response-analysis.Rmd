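---
title: "Fractional response analysis: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional response analysis: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FRAcell)
```

## The problem

A standard dose–response curve reduces each dose to the mean or median of
the single-cell responses, discarding cell-to-cell heterogeneity,
multivariate structure (several effectors measured jointly), and temporal
structure (trajectories). Fractional response analysis (FRA) replaces that
summary with two population-level quantities:

* the **fractional response curve (FRC)** `r(x_i)` — the cumulative count of
  distinct response distributions across the ordered dose series
  `x_1 < … < x_m`. Each increment `Δr_i = r(x_i) − r(x_{i−1})` is the
  fraction of dose-`i` cells whose responses differ from everything seen at
  lower doses;
* the **typical-fraction matrix** `v_ij` — the fraction of cells stimulated
  with dose `i` whose responses are *typical* for dose `j`, meaning the
  conditional response density of dose `j` is the largest at that response
  value. Its off-diagonal structure is the fractional cell-to-cell
  heterogeneity, displayed as bands around the FRC or as a pie-chart matrix.

Formally, with per-dose response densities `p_k(y) = P(y | x_k)` over the
response space,

```
r(x_i) = ∫ max_{k ≤ i} p_k(y) dy,
```

and `r(x_i)` also equals the sum of the diagonal typical fractions
`v_11 + … + v_ii` computed with only the doses `x_1..x_i` in play. The FRC
has an information-theoretic reading (Rényi min-information counts
distinguishable output distributions), but everything in this package is
phrased and computed in terms of fractions of cells.

## Estimation

The densities `p_k` are never estimated. Instead the package exploits the
Bayes identity: under a **uniform dose prior** `P(x_j) = 1/m`, the posterior
`P(x_j | y)` is proportional to `p_j(y)`, so "which dose has the largest
density at `y`" equals "which dose has the largest posterior at `y`". The
posterior is approximated by multinomial logistic regression — the log-ratio
of any dose's posterior against the reference (highest) dose is assumed
linear in `y`:

```
log P(x_j | y) / P(x_m | y) ≈ α_j + β_j' y.
```

This assumption is exact for Gaussian location families with shared
covariance, which is why the Gaussian benchmarks in the test suite are the
right place to measure estimator accuracy against the exact integral.

Key implementation decisions:

* **Prefix-restricted fits.** `r(x_i)` is computed from a classifier fitted
  on doses `x_1..x_i` only ("in isolation from higher doses"), so the curve
  costs `m` fits. A single all-dose fit would let cells be claimed by doses
  not yet under consideration and break the equivalence with the
  max-density integral; the all-dose fit is reused only for the
  heterogeneity matrix attached for display.
* **Uniform prior via class-balanced weights.** Each dose contributes equal
  total weight to the likelihood regardless of `n_i`, which is
  deterministic and uses every cell (subsampling to equal counts would
  discard data and need a seed). Duplicating all cells of one dose
  therefore moves estimates only by sampling noise — a property the test
  suite checks.
* **Fitting.** `nnet::multinom` with fixed solver settings (relative
  tolerance 1e-8, default iteration cap 1000) on a convex penalized
  likelihood: refits are bit-reproducible. A small ridge penalty (default
  1e-4) keeps coefficients finite when doses are perfectly separable; the
  argmax assignment is insensitive to a penalty of this size. The penalty
  applies to intercepts as well as slopes — at 1e-4 the difference from
  leaving intercepts unpenalized is far below every tolerance used here,
  and reusing the standard fitter was preferred over a custom solver.
* **Ties to the lowest dose.** Posteriors equal within 1e-12 are assigned
  to the lowest dose index. This makes "identical response distributions →
  FRC = 1" hold exactly, matching the reading of the FRC as a count of
  *distinct* distributions, and the oracle uses the same rule so the two
  routes agree. For the continuous families shipped here tie sets have
  measure zero.
* **Resubstitution by default.** `v_ij` sums indicator functions over the
  measured cells — the defining formula — so the classifier is evaluated on
  its own training cells. That is optimistic when `d` is large relative to
  `n_i`; a stratified 10-fold cross-validated assignment (`cv = TRUE`,
  deterministic round-robin folds within each dose, so no extra seed) is
  available for those settings.
* **Negative increments.** With estimated classifiers `Δr_i` can be
  fractionally negative by sampling noise; values are reported as computed
  and a warning flags increments below −0.02 as estimation-quality
  failures.

Uncertainty comes from a stratified bootstrap: cells are resampled with
replacement within each dose (every `n_i` preserved, so no dose can drop
out), the full prefix-fit pipeline is rerun per replicate, and per-dose
empirical quantiles of `r` and of each `v_ij` are attached. The displayed
heterogeneity bands themselves are point-estimate fractions; bootstrap
envelopes are drawn separately.

## The exact-Bayes oracle

For known parametric per-dose distributions the package computes the ground
truth directly, giving an independent yardstick for every estimator test:

* univariate models: the support is partitioned into segments on which the
  density argmax is constant (boundaries located on an 8192-point grid and
  refined by root-finding; known density discontinuities such as uniform
  edges are inserted as segment boundaries), then each piece is integrated
  by adaptive quadrature. Gaussian-family supports are truncated 10
  standard deviations beyond the extreme means, a truncation error many
  orders below the 1e-6 tolerance. Reported standard error is 0.
* multivariate models: `∫ max_k p_k` is estimated by importance sampling
  from the equal-weight mixture of the prefix distributions — a proposal
  that covers the support of the integrand and gives finite-variance
  weights `max_k p_k / mean_k p_k ∈ [1, i]` — with the Monte-Carlo standard
  error reported; typical fractions use direct draws from each row
  distribution.

The identity "integral of the pointwise maximum = prefix diagonal sum"
holds by construction in the quadrature path and is asserted to 1e-4 across
five univariate model families in the tests.

## What the simulator emulates

`simulateDoseResponse()` produces datasets with known ground truth in the
regimes FRA is meant to distinguish. Defaults were chosen once to look like
the corresponding experimental settings and are not tuned per test:

* **graded** (IFN-γ-like nuclear pSTAT1 by immunostaining): per-dose
  lognormal, `meanlog = 1.5 + log10(1 + x/1)`, `sdlog = 0.5`, doses 0, 1,
  10, 100, 1000 (ng/mL scale), 1000 cells/dose. The whole distribution
  shifts up with dose.
* **binary** (IL-10-like pSTAT3): lognormal mixture with fixed "off"
  (meanlog 1.5) and "on" (meanlog 3.5) components and a Hill on-fraction
  `p(x) = x/(x + 10)`; dose mainly moves cells between states.
* **multivariate** (PBMC-like joint pSTAT panel): 5 jointly Gaussian
  effectors, means `log10(1 + x/K_j)` with per-effector half-saturation
  doses `K = (5, 10, 25, 50, 100)` so sensitivities differ across features,
  sd 0.6 with exchangeable correlation 0.3, doses 0, 25, 250, 2500 (U/mL
  scale).
* **trajectory** (NF-κB nuclear/cytoplasmic ratio under TNF-α): 21 frames
  at 3-min spacing over 60 min, mean `1 + a(x) (t/18) exp(1 − t/18)`
  peaking at 18 min with saturating amplitude `a(x) = 2x/(x + 0.1)`, and
  heteroscedastic noise `0.1 + 0.2·(mean − baseline)`, independent across
  frames. 500 cells/dose.
* **logdose** (Weber–Fechner regime): univariate Gaussian with mean
  `2·log10(1 + x)` and sd 1 over doses `10^1..10^5` — mean spacing two
  standard deviations per decade, so ground-truth FRC increments per
  decade are nearly equal and the curve is linear in `log10(dose)`.

What the simulator deliberately does **not** reproduce: mass-cytometry
measurement artifacts (spillover, debarcoding, zero-inflation), frame-to-
frame autocorrelation in trajectories (FRA treats frames as generic
coordinates, so independent noise exercises the estimator equally), batch
or replicate effects, and any mechanistic receptor/STAT kinetics. Passing
tests therefore demonstrate correctness of the estimator under its own
modeling assumptions, not robustness to instrument-specific noise.

## Numerical and interface choices

* Responses are accepted as delimited text (one row per cell, numeric dose
  column); doses are keyed by exact numeric value, replicate rows for the
  same dose pool, and dose 0 (the control) is an ordinary level. Rows with
  non-finite responses are dropped with a warning — FRA has no missing-data
  model, so imputation is not offered.
* The response transform (none / `log1p` / `arcsinh` with cofactor) is
  explicit and recorded in the dataset and in the run metadata, never
  implicit: classification results depend on it. `arcsinh` cofactor 5 is
  the customary mass-cytometry choice, `log1p` suits fluorescence; the
  default is no transform.
* `validateForFRA()` warns (never fails) when cells per dose fall under 10
  per response dimension, under 25 in total, or when only one dose is
  present — regimes where classifier-based fraction estimates are
  unreliable.
* Dose values never enter the estimator numerically (classes only), so
  rescaling doses changes nothing but the plot axis; a zero dose is drawn
  one decade below the smallest nonzero dose on the log axis.
* Band stacking order in the FRC display is outward by dose distance
  |j − i|, a readability convention; pie wedges start at 12 o'clock and run
  clockwise in dose order.

## Problem sizes used in validation

The test suite and the acceptance script validate on: the three-Gaussian
location benchmark N(0,1)/N(2,1)/N(4,1) at 2000 cells/dose (estimator vs
closed-form Φ values, tolerance ±0.05); disjoint uniforms at 500
cells/dose (±0.01); identical distributions at 1500 cells/dose (±0.1);
five univariate families for the decomposition identity (1e-4); the
logdose scenario at 2000 cells/dose for log-linearity (R² ≥ 0.95) and
near-equal oracle increments (within 10%); and bootstrap reproducibility
at B = 8–60. These sizes were chosen so each check is decisively inside
its tolerance at the default parameters.

## Worked example

```{r example, eval = FALSE}
sim <- simulateDoseResponse("graded", seed = 1)
frc <- fractionalResponseCurve(sim$data)
frcValues(frc)
fractionValues(heterogeneity(frc))
exactFRC(sim$model)          # ground truth for comparison
plotFRC(frc)
plotHeterogeneityPies(heterogeneity(frc))
```

## Known limitations

* Logistic posteriors are exact only when log-density ratios are linear in
  `y`; strongly curved boundaries (e.g. equal-mean, different-variance
  doses) are approximated by their best linear separator, biasing `v` and
  `r` toward 1. Other classifiers could stand behind the same interface but
  are intentionally not shipped.
* Resubstitution optimism grows with `d/n_i`; use `cv = TRUE` and heed
  `validateForFRA()` in high-dimensional, low-count settings.
* The estimated FRC is not forced monotone; small negative increments are
  honest estimation noise and are flagged, not clipped (beyond the [1, i]
  range guard).
* The oracle's univariate quadrature assumes piecewise-smooth densities
  with at most finitely many argmax changes on the declared support.
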