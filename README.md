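# FRAcell

Fractional response analysis (FRA) of single-cell dose–response data.

## The problem

Single-cell dose–response experiments — phospho-STAT levels by cytometry,
joint multi-effector panels, or NF-κB trajectories from live imaging —
are usually summarized by a mean/median dose–response curve, which hides
cell-to-cell heterogeneity and cannot handle multivariate or time-series
responses. FRAcell instead quantifies, for an ordered dose series
`x_1 < … < x_m` with per-dose response distributions `p_k(y) = P(y | x_k)`:

* the **fractional response curve (FRC)**

  `r(x_i) = ∫ max_{k ≤ i} p_k(y) dy`

  — the cumulative count of distinct response distributions up to dose i.
  Its increment `Δr_i` is the fraction of dose-i cells whose responses
  differ from everything seen at lower doses; `r(x_1) = 1` by definition.

* the **typical-fraction matrix** `v_ij` — the fraction of cells stimulated
  with dose i whose responses are *typical* for dose j (dose j's density is
  largest there). Rows sum to 1; the off-diagonal structure is the
  fractional cell-to-cell heterogeneity, drawn as bands around the FRC or
  as a pie-chart matrix.

Neither quantity requires density estimation: under a uniform dose prior,
"largest conditional density" equals "largest posterior", and the posterior
is estimated by multinomial logistic regression
(`log P(x_j|y)/P(x_m|y) ≈ α_j + β_j' y`), fitted with class-balanced
weights so the uniform prior holds regardless of per-dose cell counts.
`r(x_i)` is the diagonal sum `v_11 + … + v_ii` of a classifier fitted on
doses `x_1..x_i` only. It works identically for univariate, multivariate,
and trajectory responses (each time point one coordinate).

The package is for experimentalists and modelers analyzing cytokine-type
dose–response panels who want a heterogeneity-aware, classifier-based
alternative to mean-response curves, with exact-Bayes oracles and synthetic
generators to validate the estimator.

## Worked example

```r
library(FRAcell)

sim <- simulateDoseResponse("graded", seed = 1)   # IFN-γ-like, 5 doses, 1000 cells/dose
frc <- fractionalResponseCurve(sim$data)
frc
#> FRCResult over 5 dose(s)
#>  dose     r delta_r
#>     0 1.000   0.000
#>     1 1.213   0.213
#>    10 1.745   0.532
#>   100 2.375   0.630
#>  1000 3.029   0.654
```

Between dose 10 and 100, `delta_r = 0.630`: 63% of the cells at dose 100
respond differently from every lower dose. In total the five doses induce
about 3 distinct response distributions. The exact ground truth for this
generator, `exactFRC(sim$model)$frc`, is `1.000 1.237 1.778 2.442 3.123` —
the estimate tracks it within a few percent.

```r
round(fractionValues(heterogeneity(frc)), 3)
#>          0     1    10   100  1000
#> 0    0.703 0.227 0.069 0.001 0.000
#> 1    0.490 0.331 0.174 0.005 0.000
#> 10   0.067 0.221 0.568 0.144 0.000
#> 100  0.000 0.012 0.219 0.641 0.128
#> 1000 0.000 0.000 0.002 0.212 0.786
```

Row "1": 49% of dose-1 cells respond like unstimulated controls, 33% are
typical for their own dose, 17% look like dose-10 cells. Display with
`plotFRC(frc)` (bands around the curve: higher-dose-typical fractions
above, lower below) and `plotHeterogeneityPies(heterogeneity(frc))`.

A command-line entry point wraps the same pipeline:

```sh
Rscript inst/scripts/fra.R simulate --scenario graded --out-dir simdata --seed 1
Rscript inst/scripts/fra.R run --input simdata/dataset.csv --out-dir results --bootstrap 200
Rscript inst/scripts/fra.R plot --out-dir results --format pdf
```

`run` writes `frc.csv`, `heterogeneity.csv`, a `metadata.txt` echo of every
resolved setting, and both figures.

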