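test_that("separable doses give an identity typical-fraction matrix", {
    dre <- makeDisjointUniformDRE(m = 2L, n = 500, seed = 1)
    fit <- fitPosteriorModel(dre)
    v <- typicalFractionMatrix(dre, fit)
    expect_equal(unname(fractionValues(v)), diag(2), tolerance = 1e-12)
})

test_that("overlapping Gaussians split at the Bayes boundary", {
    # N(0,1) vs N(2,1): mass on each side of the boundary at y = 1 is
    # pnorm(1) = 0.8413
    dre <- makeGaussianDRE(c(0, 2), n = 5000, seed = 13)
    fit <- fitPosteriorModel(dre)
    v <- fractionValues(typicalFractionMatrix(dre, fit))
    expect_equal(unname(v),
                 matrix(c(0.8413, 0.1587, 0.1587, 0.8413), 2, byrow = TRUE),
                 tolerance = 0.02)
})

test_that("typical-fraction rows always sum to one", {
    fixtures <- list(
        makeGaussianDRE(c(0, 1, 2), n = 200, seed = 2),
        makeDisjointUniformDRE(m = 3L, n = 100, seed = 3),
        simulateDoseResponse("binary", cellsPerDose = 200, seed = 4)$data)
    for (dre in fixtures) {
        v <- typicalFractionMatrix(dre, fitPosteriorModel(dre))
        expect_equal(unname(rowSums(fractionValues(v))),
                     rep(1, length(doseLevels(dre))), tolerance = 1e-12)
        expect_identical(unname(cellsPerDose(v)),
                         unname(cellsPerDose(dre)))
    }
})

test_that("identical distributions collapse onto the lowest dose", {
    dre <- makeGaussianDRE(c(0, 0, 0), n = 1500, seed = 5)
    frc <- fractionalResponseCurve(dre)
    expect_equal(unname(frcValues(frc)), c(1, 1, 1), tolerance = 0.1)
})

test_that("the FRC counts distinct distributions", {
    one <- makeGaussianDRE(0, n = 100, seed = 6)
    expect_identical(unname(frcValues(fractionalResponseCurve(one))), 1)

    sep <- makeDisjointUniformDRE(m = 3L, n = 500, seed = 7)
    expect_equal(unname(frcValues(fractionalResponseCurve(sep))),
                 c(1, 2, 3), tolerance = 0.01)

    g3 <- makeGaussianDRE(c(0, 2, 4), n = 2000, seed = 8)
    expect_equal(unname(frcValues(fractionalResponseCurve(g3))),
                 threeGaussianExactFRC, tolerance = 0.05)
})

test_that("FRC invariants hold across fixtures", {
    fixtures <- list(
        makeGaussianDRE(c(0, 1.5, 3), n = 400, seed = 9),
        simulateDoseResponse("graded", cellsPerDose = 300, seed = 10)$data,
        simulateDoseResponse("binary", cellsPerDose = 300, seed = 11)$data)
    for (dre in fixtures) {
        frc <- fractionalResponseCurve(dre)
        r <- unname(frcValues(frc))
        m <- length(r)
        expect_identical(r[1L], 1)
        expect_true(all(r >= 1 - 1e-9 & r <= seq_len(m) + 1e-9))
        expect_true(all(frcIncrements(frc) > -0.02))
        expect_equal(unname(rowSums(fractionValues(heterogeneity(frc)))),
                     rep(1, m), tolerance = 1e-12)
    }
})

test_that("duplicating one dose's cells barely moves the estimate", {
    # the class-balanced fit targets the uniform prior, so inflating n_i
    # must not shift fractions beyond sampling noise
    dre <- makeGaussianDRE(c(0, 2, 4), n = 600, seed = 12)
    y <- responses(dre); dose <- doseIndex(dre)
    dup <- c(seq_len(ncol(dre)), which(dose == 2L))
    dre2 <- DoseResponseExperiment(y[dup, , drop = FALSE],
                                   colData(dre)$dose[dup])
    r1 <- unname(frcValues(fractionalResponseCurve(dre)))
    r2 <- unname(frcValues(fractionalResponseCurve(dre2)))
    expect_lt(max(abs(r1 - r2)), 0.03)
    v1 <- fractionValues(heterogeneity(fractionalResponseCurve(dre)))
    v2 <- fractionValues(heterogeneity(fractionalResponseCurve(dre2)))
    expect_lt(max(abs(v1 - v2)), 0.03)
})

test_that("shuffling dose labels drives the FRC to the null of 1", {
    dre <- makeGaussianDRE(c(0, 2, 4), n = 700, seed = 14)
    set.seed(77)
    shuffled <- DoseResponseExperiment(responses(dre),
                                       sample(colData(dre)$dose))
    r <- unname(frcValues(fractionalResponseCurve(shuffled)))
    expect_true(all(abs(r - 1) < 0.1))
})

test_that("dose values act only as labels", {
    dre <- makeGaussianDRE(c(0, 2, 4), n = 400, doses = c(0, 25, 250),
                           seed = 15)
    scaled <- DoseResponseExperiment(responses(dre),
                                     colData(dre)$dose * 1000)
    r1 <- unname(frcValues(fractionalResponseCurve(dre)))
    r2 <- unname(frcValues(fractionalResponseCurve(scaled)))
    expect_identical(r1, r2)
})

test_that("cross-validated assignment agrees with resubstitution here", {
    # ample cells per dimension: CV pessimism should be negligible
    dre <- makeGaussianDRE(c(0, 2, 4), n = 900, seed = 16)
    r <- unname(frcValues(fractionalResponseCurve(dre)))
    rcv <- unname(frcValues(fractionalResponseCurve(dre, cv = TRUE)))
    expect_equal(rcv, r, tolerance = 0.05)
})

test_that("bootstrap bands are reproducible and collapse at B = 1", {
    dre <- makeGaussianDRE(c(0, 2), n = 300, seed = 17)
    b1 <- bootstrapFRA(dre, B = 1L, seed = 5)
    bb <- bootstrapBands(b1)
    expect_equal(bb$frcLower, bb$frcUpper)     # one replicate, both quantiles
    b2 <- bootstrapFRA(dre, B = 10L, seed = 5)
    b3 <- bootstrapFRA(dre, B = 10L, seed = 5)
    expect_identical(bootstrapBands(b2), bootstrapBands(b3))
    expect_identical(unname(frcValues(b2)),
                     unname(frcValues(fractionalResponseCurve(dre))))
})

test_that("bootstrap bands cover the exact-Bayes FRC", {
    dre <- makeGaussianDRE(c(0, 2, 4), n = 1000, seed = 18)
    b <- bootstrapFRA(dre, B = 60L, seed = 19)
    bb <- bootstrapBands(b)
    expect_true(all(threeGaussianExactFRC >= bb$frcLower - 1e-9))
    expect_true(all(threeGaussianExactFRC <= bb$frcUpper + 1e-9))
})
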