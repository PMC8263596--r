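Package: FRAcell
Title: Fractional Response Analysis of Single-Cell Dose-Response Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fractional response analysis (FRA) for single-cell dose-response
    experiments. Given per-cell responses (one or several signaling effectors,
    or a trajectory sampled at multiple time points) measured across an ordered
    dose series, FRAcell estimates the fractional response curve (the
    cumulative count of distinct response distributions) and the fractional
    cell-to-cell heterogeneity matrix of dose-typical response fractions, using
    multinomial logistic regression to approximate dose posteriors under a
    uniform dose prior. Exact-Bayes reference computations for parametric
    response models, synthetic dose-response generators for graded, binary,
    multivariate, trajectory, and log-dose scenarios, stratified bootstrap
    uncertainty bands, and the band-plot and pie-chart-matrix displays are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, graphics, grDevices, tools, nnet, S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: SingleCell, Classification, FlowCytometry, Software
RoxygenNote: 7.3.3
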