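test_that("every shipped 1-D density integrates to one", {
    models <- list(
        gaussianDoseModel(c(0, 1), means = c(0, 2)),
        uniformDoseModel(c(0, 1), mins = c(0, 2), maxs = c(1, 3)),
        lognormalDoseModel(c(0, 1), meanlogs = c(1, 2)),
        binaryMixtureDoseModel(c(0, 1), onFraction = c(0.2, 0.8)))
    for (mod in models)
        for (dd in mod@distributions)
            expect_equal(integrate(dd$pdf, mod@support[1L], mod@support[2L],
                                   rel.tol = 1e-9)$value, 1,
                         tolerance = 1e-6)
})

test_that("samplers match their densities (KS sanity)", {
    set.seed(3)
    g <- gaussianDoseModel(0, means = 1.5, sds = 2)
    expect_gt(ks.test(g@distributions[[1L]]$sample(2000),
                      pnorm, mean = 1.5, sd = 2)$p.value, 0.01)
    l <- lognormalDoseModel(0, meanlogs = 1, sdlogs = 0.4)
    expect_gt(ks.test(l@distributions[[1L]]$sample(2000),
                      plnorm, meanlog = 1, sdlog = 0.4)$p.value, 0.01)
})

test_that("exact FRC hits closed forms", {
    id <- gaussianDoseModel(c(0, 1, 2), means = c(1, 1, 1))
    expect_equal(exactFRC(id)$frc, c(1, 1, 1), tolerance = 1e-9)

    disj <- uniformDoseModel(c(0, 1, 2), mins = c(0, 2, 4),
                             maxs = c(1, 3, 5))
    expect_equal(exactFRC(disj)$frc, c(1, 2, 3), tolerance = 1e-9)

    pair <- gaussianDoseModel(c(0, 1), means = c(0, 2))
    expect_equal(exactFRC(pair)$frc, c(1, 2 - 2 * pnorm(-1)),
                 tolerance = 1e-4)
})

test_that("exact typical fractions hit closed forms and tie rules", {
    pair <- gaussianDoseModel(c(0, 1), means = c(0, 2))
    v <- fractionValues(exactTypicalFractions(pair))
    expect_equal(unname(v),
                 matrix(c(pnorm(1), pnorm(-1), pnorm(-1), pnorm(1)), 2,
                        byrow = TRUE), tolerance = 1e-4)

    id3 <- gaussianDoseModel(c(0, 1, 2), means = c(0, 0, 0))
    v3 <- fractionValues(exactTypicalFractions(id3))
    expect_equal(unname(v3[, 1L]), rep(1, 3), tolerance = 1e-9)

    disj <- uniformDoseModel(c(0, 1, 2), mins = c(0, 2, 4),
                             maxs = c(1, 3, 5))
    expect_equal(unname(fractionValues(exactTypicalFractions(disj))),
                 diag(3), tolerance = 1e-9)
})

test_that("the max-density integral equals the prefix diagonal sum", {
    # the two routes to the FRC — integrating the pointwise maximum density
    # and summing prefix-restricted diagonal typical fractions — are the
    # same quantity
    models <- list(
        gaussianDoseModel(c(0, 1, 2), means = c(0, 2, 4)),
        gaussianDoseModel(c(0, 1, 2, 3), means = c(0, 1, 1.5, 4),
                          sds = c(1, 1.2, 0.8, 1)),
        uniformDoseModel(c(0, 1, 2), mins = c(0, 0.5, 4),
                         maxs = c(1, 3, 5)),
        lognormalDoseModel(c(0, 1, 10, 100),
                           meanlogs = 1.5 + log10(1 + c(0, 1, 10, 100))),
        binaryMixtureDoseModel(c(0, 1, 10, 100),
                               onFraction = c(0, 0.1, 0.5, 0.9)))
    for (mod in models) {
        frc <- exactFRC(mod)$frc
        diags <- vapply(seq_along(frc), function(i)
            sum(diag(fractionValues(
                exactTypicalFractions(mod, doseSubset = seq_len(i))))),
            numeric(1L))
        expect_equal(frc, diags, tolerance = 1e-4)
    }
})

test_that("the exact FRC is non-decreasing and bounded", {
    mod <- binaryMixtureDoseModel(c(0, 1, 10, 100, 1000),
                                  onFraction = c(0, 0.09, 0.5, 0.91, 0.99))
    frc <- exactFRC(mod)$frc
    expect_true(all(diff(frc) >= -1e-9))
    expect_true(all(frc >= 1 - 1e-9 & frc <= seq_along(frc) + 1e-9))
})

test_that("Monte-Carlo and quadrature integration paths agree", {
    # embed a 1-D Gaussian family as dimension 1 of a 2-D model whose
    # second coordinate is identical across doses: the FRC is unchanged,
    # but the 2-D model takes the Monte-Carlo path
    mu <- c(0, 2, 4)
    quad <- exactFRC(gaussianDoseModel(c(0, 1, 2), means = mu))
    mv <- mvGaussianDoseModel(c(0, 1, 2), cbind(mu, 0), diag(2))
    mc <- exactFRC(mv, mcSamples = 4e4, seed = 6)
    expect_true(all(abs(mc$frc - quad$frc) <= 3 * pmax(mc$se, 1e-12) + 1e-9))
    expect_true(all(mc$se[-1L] > 0))
})

test_that("multivariate typical fractions renormalize and use the tie rule", {
    mv <- mvGaussianDoseModel(c(0, 1), rbind(c(0, 0), c(0, 0)), diag(2))
    v <- fractionValues(exactTypicalFractions(mv, mcSamples = 2000, seed = 2))
    expect_equal(unname(v[, 1L]), c(1, 1))   # identical => lowest dose
    expect_equal(unname(rowSums(v)), c(1, 1), tolerance = 1e-12)
})
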