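# fixtures are generated in code; seeds fixed per call site

# Gaussian-location dataset: one feature, equal-variance classes
makeGaussianDRE <- function(means, n = 500L, sds = 1, doses = NULL,
                            seed = 1L) {
    m <- length(means)
    sds <- rep_len(sds, m)
    if (is.null(doses)) doses <- seq_len(m) - 1
    set.seed(seed)
    y <- unlist(lapply(seq_len(m), function(i) rnorm(n, means[i], sds[i])))
    DoseResponseExperiment(y, rep(doses, each = n))
}

# disjoint uniform supports U(0,1), U(2,3), U(4,5), ...
makeDisjointUniformDRE <- function(m = 3L, n = 500L, seed = 1L) {
    set.seed(seed)
    y <- unlist(lapply(seq_len(m), function(i)
        runif(n, 2 * (i - 1), 2 * (i - 1) + 1)))
    DoseResponseExperiment(y, rep(seq_len(m) - 1, each = n))
}

# the three-Gaussian benchmark N(0,1), N(2,1), N(4,1) and its exact FRC
threeGaussianModel <- function() gaussianDoseModel(c(0, 1, 2),
                                                   means = c(0, 2, 4))
# closed forms: r2 = 2 - 2*pnorm(-1), r3 = 3*pnorm(1) - pnorm(-1)
threeGaussianExactFRC <- c(1, 1.6826895, 2.3653790)

writeTempCSV <- function(df, sep = ",") {
    path <- tempfile(fileext = ".csv")
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    path
}
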