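#' Fit the multinomial-logistic dose posterior
#'
#' Fits a multinomial logistic regression of dose class on the response
#' vector, over a selected subset of doses, by penalized maximum likelihood
#' (\code{nnet::multinom}). Each dose contributes equal total weight to the
#' fit (class-balanced observation weights), so the fitted posterior
#' corresponds to a uniform dose prior regardless of per-dose cell counts —
#' under that prior the posterior ordering of doses equals the ordering of
#' the conditional response densities, which is what dose-typicality needs.
#' A small ridge penalty (default 1e-4) keeps coefficients finite when doses
#' are perfectly separable; the maximum-posterior assignment is insensitive
#' to a penalty of this magnitude.
#'
#' The optimizer settings (BFGS via \code{nnet}, relative tolerance 1e-8) are
#' fixed, and the penalized likelihood is convex, so refitting on identical
#' input reproduces identical coefficients.
#'
#' @param x a \linkS4class{DoseResponseExperiment}.
#' @param doseSubset integer indices into \code{doseLevels(x)} (default: all
#'   doses), ascending.
#' @param regularization nonnegative ridge penalty on the coefficients.
#' @param maxIterations optimizer iteration cap.
#' @return a \linkS4class{PosteriorModel}. With a single selected dose the
#'   degenerate model whose posterior is identically 1 is returned.
#' @examples
#' sim <- simulateDoseResponse("graded", cellsPerDose = 200, seed = 1)
#' fit <- fitPosteriorModel(sim$data)
#' posteriorProbs(fit, responses(sim$data)[1, ])
#' @export
fitPosteriorModel <- function(x, doseSubset = seq_along(doseLevels(x)),
                              regularization = 1e-4, maxIterations = 1000L) {
    stopifnot(is(x, "DoseResponseExperiment"))
    m <- length(doseLevels(x))
    doseSubset <- sort(unique(as.integer(doseSubset)))
    if (length(doseSubset) == 0L || any(doseSubset < 1L | doseSubset > m))
        stop("doseSubset must be nonempty indices in 1..", m)
    if (!is.numeric(regularization) || regularization < 0)
        stop("regularization must be nonnegative")

    d <- nrow(x)
    lev <- doseLevels(x)[doseSubset]
    mprime <- length(doseSubset)
    if (mprime == 1L)
        return(new("PosteriorModel", doseSubset = doseSubset,
                   doseLevels = lev, alpha = numeric(0),
                   beta = matrix(numeric(0), 0L, d), dim = as.integer(d),
                   featureNames = rownames(x),
                   transform = metadata(x)$transform,
                   regularization = regularization))

    keep <- doseIndex(x) %in% doseSubset
    y <- responses(x)[keep, , drop = FALSE]
    cls <- factor(doseIndex(x)[keep], levels = doseSubset)
    n <- table(cls)
    if (any(n == 0L))
        stop("every selected dose needs at least one cell")
    # each dose gets total weight n_tot / m'  ==> uniform prior
    w <- as.numeric(sum(n) / (mprime * n[cls]))

    df <- data.frame(.cls = cls, y, check.names = FALSE)
    fit <- nnet::multinom(.cls ~ ., data = df, weights = w,
                          decay = regularization, maxit = maxIterations,
                          reltol = 1e-8, trace = FALSE,
                          MaxNWts = (mprime) * (d + 2L) + 10L)
    if (fit$convergence != 0)
        stop("multinomial logistic fit did not converge within ",
             maxIterations, " iterations; consider a larger ",
             "regularization strength")

    # nnet reports classes 2..m' against class 1; re-express against the
    # reference (highest) class m'.
    cf <- coef(fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L,
                                       dimnames = list(NULL, names(cf)))
    full <- rbind(0, cf)                      # m' x (d+1), vs class 1
    full <- sweep(full, 2L, full[mprime, ])   # vs class m'
    new("PosteriorModel", doseSubset = doseSubset, doseLevels = lev,
        alpha = full[-mprime, 1L],
        beta = matrix(full[-mprime, -1L, drop = FALSE], mprime - 1L, d),
        dim = as.integer(d), featureNames = rownames(x),
        transform = metadata(x)$transform, regularization = regularization)
}

#' Posterior dose probabilities for response vectors
#'
#' Evaluates the fitted dose posterior at one or more response vectors: the
#' softmax of the linear scores alpha_j + beta_j' y with the reference
#' (highest selected) dose scored 0. Components are nonnegative and sum to 1.
#'
#' @param model a \linkS4class{PosteriorModel}.
#' @param y numeric vector of length d, or a cells x d matrix.
#' @return numeric vector of probabilities over the model's doses, or a
#'   matrix (cells x doses) for matrix input.
#' @export
posteriorProbs <- function(model, y) {
    stopifnot(is(model, "PosteriorModel"))
    oneRow <- is.null(dim(y))
    if (oneRow) {
        # for univariate models a bare vector is a batch of observations
        y <- if (model@dim == 1L && length(y) > 1L)
            matrix(as.numeric(y), ncol = 1L)
        else matrix(as.numeric(y), nrow = 1L)
        oneRow <- nrow(y) == 1L
    }
    y <- as.matrix(y)
    if (ncol(y) != model@dim)
        stop("response dimension ", ncol(y),
             " does not match model dimension d = ", model@dim)
    mprime <- length(model@doseSubset)
    if (mprime == 1L) {
        p <- matrix(1, nrow(y), 1L)
    } else {
        scores <- cbind(y %*% t(model@beta) +
                        rep(model@alpha, each = nrow(y)), 0)
        scores <- scores - apply(scores, 1L, max)   # overflow-safe softmax
        e <- exp(scores)
        p <- e / rowSums(e)
    }
    colnames(p) <- format(model@doseLevels, trim = TRUE)
    if (oneRow) p[1L, ] else p
}

#' Assign responses to their typical dose
#'
#' A response is typical for the dose under which it is most likely to arise;
#' under the uniform-prior posterior this is the dose of maximum posterior
#' probability. Ties (posteriors equal within 1e-12) are broken toward the
#' lowest dose, so identical response distributions collapse onto the lowest
#' dose and contribute nothing beyond the first distinct distribution.
#'
#' @param model a \linkS4class{PosteriorModel}.
#' @param y numeric vector of length d, or a cells x d matrix.
#' @return integer dose index (into the full experiment's dose levels), or a
#'   vector thereof for matrix input.
#' @export
assignTypicalDose <- function(model, y) {
    p <- posteriorProbs(model, y)
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    pick <- apply(p, 1L, function(pr)
        which(pr >= max(pr) - 1e-12)[1L])
    idx <- model@doseSubset[pick]
    if (length(idx) == 1L) idx[[1L]] else idx
}

#' @describeIn fitPosteriorModel compact display of a fitted model.
#' @param object a \linkS4class{PosteriorModel}.
#' @export
setMethod("show", "PosteriorModel", function(object) {
    cat("PosteriorModel over", length(object@doseSubset), "dose(s):",
        paste(format(object@doseLevels, trim = TRUE), collapse = ", "), "\n")
    cat("  response dimension d =", object@dim,
        "| ridge strength", object@regularization, "\n")
})
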