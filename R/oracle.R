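#' Parametric ground-truth dose-response models
#'
#' Constructors for \linkS4class{ParametricDoseResponseModel} objects holding
#' known per-dose response distributions: the inputs to the exact-Bayes
#' oracle and the ground truth paired with simulated datasets. All densities
#' are exact closed forms; samplers draw from the current RNG stream.
#'
#' @param doses ascending numeric dose values.
#' @param means,sds per-dose mean and standard deviation
#'   (\code{gaussianDoseModel}); recycled to the number of doses.
#' @param mins,maxs per-dose uniform bounds (\code{uniformDoseModel}).
#' @param meanlogs,sdlogs per-dose log-scale location and scale
#'   (\code{lognormalDoseModel}).
#' @param onFraction per-dose probability of the "on" mixture component
#'   (\code{binaryMixtureDoseModel}).
#' @param offMeanlog,offSdlog,onMeanlog,onSdlog lognormal parameters of the
#'   "off" and "on" components.
#' @param meanMatrix doses x d matrix of per-dose mean vectors
#'   (\code{mvGaussianDoseModel}, \code{trajectoryDoseModel}).
#' @param sigma covariance matrix (d x d), shared across doses
#'   (\code{mvGaussianDoseModel}).
#' @param sdMatrix doses x d matrix of per-coordinate standard deviations,
#'   independent coordinates (\code{trajectoryDoseModel}).
#' @return a \linkS4class{ParametricDoseResponseModel}.
#' @name parametricModels
NULL

.newParametric <- function(doses, distributions, dim, support) {
    new("ParametricDoseResponseModel", doseLevels = as.numeric(doses),
        distributions = distributions, dim = as.integer(dim),
        support = as.numeric(support))
}

#' @rdname parametricModels
#' @export
gaussianDoseModel <- function(doses, means, sds = 1) {
    m <- length(doses)
    means <- rep_len(means, m); sds <- rep_len(sds, m)
    dists <- lapply(seq_len(m), function(i) {
        mu <- means[i]; s <- sds[i]
        list(pdf = function(y) stats::dnorm(y, mu, s),
             sample = function(n) stats::rnorm(n, mu, s),
             mean = mu)
    })
    # tails truncated 10 SD beyond the extreme means: truncation error far
    # below quadrature tolerance
    .newParametric(doses, dists, 1L,
                   c(min(means) - 10 * max(sds), max(means) + 10 * max(sds)))
}

#' @rdname parametricModels
#' @export
uniformDoseModel <- function(doses, mins, maxs) {
    m <- length(doses)
    mins <- rep_len(mins, m); maxs <- rep_len(maxs, m)
    dists <- lapply(seq_len(m), function(i) {
        a <- mins[i]; b <- maxs[i]
        list(pdf = function(y) stats::dunif(y, a, b),
             sample = function(n) stats::runif(n, a, b),
             mean = (a + b) / 2, breaks = c(a, b))
    })
    .newParametric(doses, dists, 1L, c(min(mins), max(maxs)))
}

#' @rdname parametricModels
#' @export
lognormalDoseModel <- function(doses, meanlogs, sdlogs = 0.5) {
    m <- length(doses)
    meanlogs <- rep_len(meanlogs, m); sdlogs <- rep_len(sdlogs, m)
    dists <- lapply(seq_len(m), function(i) {
        mu <- meanlogs[i]; s <- sdlogs[i]
        list(pdf = function(y) stats::dlnorm(y, mu, s),
             sample = function(n) stats::rlnorm(n, mu, s),
             mean = exp(mu + s^2 / 2))
    })
    hi <- exp(max(meanlogs) + 10 * max(sdlogs))
    .newParametric(doses, dists, 1L, c(0, hi))
}

#' @rdname parametricModels
#' @export
binaryMixtureDoseModel <- function(doses, onFraction, offMeanlog = 1.5,
                                   offSdlog = 0.5, onMeanlog = 3.5,
                                   onSdlog = 0.5) {
    m <- length(doses)
    onFraction <- rep_len(onFraction, m)
    stopifnot(all(onFraction >= 0 & onFraction <= 1))
    dists <- lapply(seq_len(m), function(i) {
        p <- onFraction[i]
        list(pdf = function(y)
                 (1 - p) * stats::dlnorm(y, offMeanlog, offSdlog) +
                 p * stats::dlnorm(y, onMeanlog, onSdlog),
             sample = function(n) {
                 on <- stats::runif(n) < p
                 ifelse(on, stats::rlnorm(n, onMeanlog, onSdlog),
                        stats::rlnorm(n, offMeanlog, offSdlog))
             },
             mean = (1 - p) * exp(offMeanlog + offSdlog^2 / 2) +
                 p * exp(onMeanlog + onSdlog^2 / 2))
    })
    hi <- exp(max(offMeanlog, onMeanlog) + 10 * max(offSdlog, onSdlog))
    .newParametric(doses, dists, 1L, c(0, hi))
}

# multivariate normal density (rows of y), via the Cholesky factor
.dmvnorm <- function(y, mean, cholSigma) {
    y <- sweep(as.matrix(y), 2L, mean)
    z <- backsolve(cholSigma, t(y), transpose = TRUE)
    logdet <- 2 * sum(log(diag(cholSigma)))
    exp(-0.5 * colSums(z^2) - 0.5 * (ncol(y) * log(2 * pi) + logdet))
}

#' @rdname parametricModels
#' @export
mvGaussianDoseModel <- function(doses, meanMatrix, sigma) {
    meanMatrix <- as.matrix(meanMatrix)
    m <- length(doses)
    stopifnot(nrow(meanMatrix) == m)
    d <- ncol(meanMatrix)
    sigma <- as.matrix(sigma)
    stopifnot(nrow(sigma) == d, ncol(sigma) == d)
    ch <- chol(sigma)
    dists <- lapply(seq_len(m), function(i) {
        mu <- meanMatrix[i, ]
        list(pdf = function(y) .dmvnorm(y, mu, ch),
             sample = function(n)
                 matrix(stats::rnorm(n * d), n, d) %*% ch +
                     rep(mu, each = n),
             mean = mu)
    })
    .newParametric(doses, dists, d, numeric(0))
}

#' @rdname parametricModels
#' @export
trajectoryDoseModel <- function(doses, meanMatrix, sdMatrix) {
    meanMatrix <- as.matrix(meanMatrix)
    sdMatrix <- as.matrix(sdMatrix)
    m <- length(doses)
    d <- ncol(meanMatrix)
    stopifnot(nrow(meanMatrix) == m, all(dim(sdMatrix) == dim(meanMatrix)),
              all(sdMatrix > 0))
    dists <- lapply(seq_len(m), function(i) {
        mu <- meanMatrix[i, ]; s <- sdMatrix[i, ]
        list(pdf = function(y) {
                 y <- as.matrix(y)
                 exp(rowSums(stats::dnorm(y, rep(mu, each = nrow(y)),
                                          rep(s, each = nrow(y)),
                                          log = TRUE)))
             },
             sample = function(n)
                 matrix(stats::rnorm(n * d, rep(mu, each = n),
                                     rep(s, each = n)), n, d),
             mean = mu)
    })
    .newParametric(doses, dists, d, numeric(0))
}

# ---------------------------------------------------------------------------
# exact-Bayes computations

# partition the 1-D support into maximal segments on which the density
# argmax (ties to lowest index) is constant; boundaries refined by uniroot
.argmaxSegments <- function(pdfs, support, gridN = 8192L,
                            breaks = numeric(0)) {
    grid <- seq(support[1L], support[2L], length.out = gridN)
    dens <- vapply(pdfs, function(f) f(grid), numeric(gridN))
    lab <- apply(dens, 1L, function(p)
        which(p >= max(p) * (1 - 1e-12))[1L])
    cut <- which(diff(lab) != 0L)
    bounds <- support[1L]
    for (k in cut) {
        a <- lab[k]; b <- lab[k + 1L]
        f <- function(y) pdfs[[a]](y) - pdfs[[b]](y)
        lo <- grid[k]; hi <- grid[k + 1L]
        root <- tryCatch({
            if (sign(f(lo)) * sign(f(hi)) <= 0)
                stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
            else (lo + hi) / 2          # discontinuous density boundary
        }, error = function(e) (lo + hi) / 2)
        bounds <- c(bounds, root)
    }
    bounds <- c(bounds, support[2L])
    # merge density discontinuities (e.g. uniform edges) so each segment's
    # integrand is smooth
    breaks <- breaks[breaks > support[1L] & breaks < support[2L]]
    bounds <- sort(unique(c(bounds, breaks)))
    mids <- (bounds[-1L] + bounds[-length(bounds)]) / 2
    labels <- vapply(mids, function(y0) {
        p <- vapply(pdfs, function(f) f(y0), numeric(1L))
        which(p >= max(p) * (1 - 1e-12))[1L]
    }, integer(1L))
    list(lower = bounds[-length(bounds)], upper = bounds[-1L],
         label = labels)
}

.quadrature <- function(f, lo, hi) {
    if (hi <= lo) return(0)
    stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 1e-12,
                     subdivisions = 500L, stop.on.error = FALSE)$value
}

#' Exact fractional response curve of a parametric model
#'
#' Computes the ground-truth FRC for known per-dose densities: for each dose
#' prefix i, the integral over the response space of the pointwise maximum of
#' the prefix densities max_{k <= i} p_k(y). For univariate models this is
#' done by adaptive quadrature over the argmax partition of the support
#' (reported standard error 0); for multivariate models by importance
#' sampling from the equal-weight mixture of the prefix distributions, a
#' finite-variance, support-covering proposal, with the Monte-Carlo standard
#' error reported.
#'
#' This is the independent reference against which the classifier-based
#' estimator \code{\link{fractionalResponseCurve}} is validated.
#'
#' @param model a \linkS4class{ParametricDoseResponseModel}.
#' @param mcSamples Monte-Carlo draws per prefix (multivariate models).
#' @param seed RNG seed for the Monte-Carlo path.
#' @return data.frame with columns \code{dose}, \code{frc}, \code{se}.
#' @examples
#' exactFRC(gaussianDoseModel(c(0, 1), means = c(0, 2)))  # 1, 2 - 2*pnorm(-1)
#' @export
exactFRC <- function(model, mcSamples = 1e5L, seed = 1L) {
    stopifnot(is(model, "ParametricDoseResponseModel"))
    m <- length(model@doseLevels)
    pdfs <- lapply(model@distributions, `[[`, "pdf")
    frc <- numeric(m); se <- numeric(m)
    if (model@dim == 1L) {
        for (i in seq_len(m)) {
            seg <- .argmaxSegments(pdfs[seq_len(i)], model@support,
                                   breaks = unlist(lapply(
                                       model@distributions[seq_len(i)],
                                       `[[`, "breaks")))
            frc[i] <- sum(vapply(seq_along(seg$label), function(k)
                .quadrature(pdfs[[seg$label[k]]], seg$lower[k],
                            seg$upper[k]), numeric(1L)))
        }
    } else {
        if (mcSamples < 1e4L)
            stop("multivariate exact FRC needs mcSamples >= 10000")
        restore <- .Random.seed_exists()
        on.exit(restore())
        set.seed(seed)
        for (i in seq_len(m)) {
            comp <- sample.int(i, mcSamples, replace = TRUE)
            ys <- matrix(NA_real_, mcSamples, model@dim)
            for (k in seq_len(i)) {
                at <- comp == k
                if (any(at))
                    ys[at, ] <- model@distributions[[k]]$sample(sum(at))
            }
            dens <- vapply(pdfs[seq_len(i)], function(f) f(ys),
                           numeric(mcSamples))
            dens <- matrix(dens, mcSamples, i)
            w <- apply(dens, 1L, max) / rowMeans(dens)  # max p / mixture q
            frc[i] <- mean(w)
            se[i] <- stats::sd(w) / sqrt(mcSamples)
        }
    }
    data.frame(dose = model@doseLevels, frc = frc, se = se)
}

#' Exact typical-fraction matrix of a parametric model
#'
#' Ground-truth v[i, j]: the probability, under the dose-i response
#' distribution, that dose j has the largest conditional density at the
#' response (ties to the lowest dose index — the same rule as the
#' estimator's). Univariate models use the argmax-partition quadrature;
#' multivariate models use Monte-Carlo draws from each row distribution.
#'
#' @param model a \linkS4class{ParametricDoseResponseModel}.
#' @param doseSubset indices of the doses to include (default all); the
#'   argmax competition runs only over this subset, which is what the
#'   prefix-restricted FRC construction needs.
#' @param mcSamples Monte-Carlo draws per row (multivariate models).
#' @param seed RNG seed for the Monte-Carlo path.
#' @return a \linkS4class{TypicalFractionMatrix} (rows renormalized; for the
#'   quadrature path row sums are exact to integration tolerance).
#' @export
exactTypicalFractions <- function(model, doseSubset = NULL,
                                  mcSamples = 1e5L, seed = 1L) {
    stopifnot(is(model, "ParametricDoseResponseModel"))
    if (is.null(doseSubset))
        doseSubset <- seq_along(model@doseLevels)
    doseSubset <- sort(unique(as.integer(doseSubset)))
    pdfs <- lapply(model@distributions[doseSubset], `[[`, "pdf")
    mprime <- length(doseSubset)
    v <- matrix(0, mprime, mprime)
    if (model@dim == 1L) {
        seg <- .argmaxSegments(pdfs, model@support,
                               breaks = unlist(lapply(
                                   model@distributions[doseSubset],
                                   `[[`, "breaks")))
        for (i in seq_len(mprime)) {
            rowPdf <- pdfs[[i]]
            for (k in seq_along(seg$label))
                v[i, seg$label[k]] <- v[i, seg$label[k]] +
                    .quadrature(rowPdf, seg$lower[k], seg$upper[k])
        }
    } else {
        restore <- .Random.seed_exists()
        on.exit(restore())
        set.seed(seed)
        for (i in seq_len(mprime)) {
            ys <- model@distributions[[doseSubset[i]]]$sample(mcSamples)
            dens <- vapply(pdfs, function(f) f(ys), numeric(mcSamples))
            dens <- matrix(dens, mcSamples, mprime)
            lab <- apply(dens, 1L, function(p)
                which(p >= max(p) * (1 - 1e-12))[1L])
            v[i, ] <- tabulate(lab, nbins = mprime) / mcSamples
        }
    }
    v <- v / rowSums(v)
    lab <- format(model@doseLevels[doseSubset], trim = TRUE)
    dimnames(v) <- list(lab, lab)
    new("TypicalFractionMatrix", values = v,
        doseLevels = model@doseLevels[doseSubset],
        counts = rep(as.integer(mcSamples), mprime))
}

setMethod("doseLevels", "ParametricDoseResponseModel",
    function(x) x@doseLevels)

setMethod("show", "ParametricDoseResponseModel", function(object) {
    cat("ParametricDoseResponseModel:", length(object@doseLevels),
        "dose(s), dimension d =", object@dim, "\n")
    cat("  doses:", paste(format(object@doseLevels, trim = TRUE),
                          collapse = ", "), "\n")
})
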