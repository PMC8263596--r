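test_that("a delimited table parses into an ordered, counted experiment", {
    set.seed(41)
    df <- data.frame(dose = rep(c(250, 0, 25), each = 100),
                     pSTAT1 = rnorm(300, 5), pSTAT3 = rnorm(300, 2))
    path <- writeTempCSV(df)
    dre <- readDoseResponse(path, doseColumn = "dose")
    expect_s4_class(dre, "DoseResponseExperiment")
    expect_identical(doseLevels(dre), c(0, 25, 250))   # sorted ascending
    expect_identical(unname(cellsPerDose(dre)), rep(100L, 3))
    expect_identical(nrow(dre), 2L)                    # d = 2 features
    expect_identical(rownames(dre), c("pSTAT1", "pSTAT3"))
    # stable reindexing: dose-0 cells keep their within-dose input order
    orig0 <- df$pSTAT1[df$dose == 0]
    expect_equal(unname(responses(dre)[doseIndex(dre) == 1L, "pSTAT1"]),
                 orig0, tolerance = 1e-12)
})

test_that("rows with non-finite responses are dropped with a warning", {
    df <- data.frame(dose = rep(c(0, 10), each = 5),
                     y = c(1:4, NA, 6:10))
    path <- writeTempCSV(df)
    expect_warning(dre <- readDoseResponse(path), "dropped 1 cell")
    expect_identical(unname(cellsPerDose(dre)), c(4L, 5L))
})

test_that("read errors name the offending column, dose, or row", {
    df <- data.frame(dose = c(0, 1), y = c(1, 2))
    path <- writeTempCSV(df)
    expect_error(readDoseResponse(path, doseColumn = "conc"), "conc")
    expect_error(readDoseResponse(path, responseColumns = "z"), "z")
    bad <- writeTempCSV(data.frame(dose = c("0", "low"), y = c(1, 2)))
    expect_error(readDoseResponse(bad), "non-numeric dose .* row 2")
    lost <- writeTempCSV(data.frame(dose = c(0, 0, 10), y = c(1, 2, NA)))
    expect_error(readDoseResponse(lost), "no usable rows for dose 10")
    expect_error(readDoseResponse(tempfile()), "not found")
})

test_that("write/read round trip reproduces doses, counts, and responses", {
    sim <- simulateDoseResponse("multivariate", cellsPerDose = 50, seed = 8)
    path <- tempfile(fileext = ".csv")
    writeDoseResponse(sim$data, path)
    back <- readDoseResponse(path)
    expect_identical(doseLevels(back), doseLevels(sim$data))
    expect_identical(cellsPerDose(back), cellsPerDose(sim$data))
    expect_equal(responses(back), responses(sim$data), tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("transforms are exact at known points and 'none' is the identity", {
    dre <- makeGaussianDRE(c(0, 2), n = 50, seed = 5)
    expect_equal(responses(transformResponses(dre, "none")),
                 responses(dre))
    one <- DoseResponseExperiment(matrix(c(0, exp(1) - 1), ncol = 1),
                                  c(0, 1))
    expect_equal(unname(responses(transformResponses(one, "arcsinh",
                                                     cofactor = 5))[1L, 1L]),
                 0)                       # arcsinh(0) = 0
    expect_equal(unname(responses(transformResponses(one, "log1p"))[2L, 1L]),
                 1)                       # log1p(e - 1) = 1
    expect_error(transformResponses(dre, "arcsinh", cofactor = -1),
                 "positive")
    tr <- metadata(transformResponses(dre, "arcsinh", cofactor = 5))$transform
    expect_identical(tr$method, "arcsinh")
    expect_identical(tr$cofactor, 5)
})

test_that("monotone transforms preserve per-dose response rank order", {
    for (seed in 1:3) {
        set.seed(seed)
        dre <- DoseResponseExperiment(abs(rnorm(200, 4, 2)),
                                      rep(c(0, 5), each = 100))
        for (method in c("log1p", "arcsinh")) {
            tx <- transformResponses(dre, method, cofactor = 5)
            for (i in 1:2) {
                at <- doseIndex(dre) == i
                expect_identical(order(responses(tx)[at, 1L]),
                                 order(responses(dre)[at, 1L]))
            }
        }
    }
})

test_that("adequacy validation warns on thin data and never raises", {
    ok <- makeGaussianDRE(c(0, 2, 4), n = 100, seed = 2)
    expect_length(validateForFRA(ok), 0L)

    # trajectory-like: d = 21 with 100 cells/dose is under 10 cells per
    # dimension at every dose
    set.seed(3)
    y <- matrix(rnorm(300 * 21), 300, 21)
    traj <- DoseResponseExperiment(y, rep(c(0, 1, 10), each = 100))
    w <- validateForFRA(traj)
    expect_length(grep("cells per response dimension", w), 3L)

    single <- makeGaussianDRE(0, n = 50, seed = 4)
    expect_match(validateForFRA(single), "single dose", all = FALSE)
})

test_that("replicates of a dose pool and zero dose is a legal level", {
    set.seed(6)
    y <- rnorm(60)
    dre <- DoseResponseExperiment(y, rep(c(0, 10, 0), each = 20))
    expect_identical(doseLevels(dre), c(0, 10))
    expect_identical(unname(cellsPerDose(dre)), c(40L, 20L))
})
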