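#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' DoseResponseExperiment: single-cell responses across an ordered dose series
#'
#' A container for single-cell dose-response data, extending
#' \linkS4class{SummarizedExperiment}. The single assay \code{"response"}
#' holds one column per cell and one row per response feature (a signaling
#' effector level, or one time point of a trajectory). \code{colData} carries
#' the numeric \code{dose} of each cell and its \code{doseIndex} into the
#' ordered dose series; \code{metadata()} records the ordered
#' \code{doseLevels}, any original string dose labels, and the response
#' transform applied.
#'
#' The empirical per-dose samples stand in for the conditional response
#' distributions P(Y | dose) on which fractional response analysis operates.
#'
#' @section Invariants:
#' \itemize{
#'   \item \code{doseLevels} strictly increasing, one or more levels;
#'   \item every dose level has at least one cell;
#'   \item all response values finite;
#'   \item response dimension identical for all cells (matrix layout).
#' }
#'
#' @seealso \code{\link{DoseResponseExperiment}} (constructor),
#'   \code{\link{readDoseResponse}}, \code{\link{fractionalResponseCurve}}
#' @export
setClass("DoseResponseExperiment", contains = "SummarizedExperiment")

setValidity("DoseResponseExperiment", function(object) {
    msg <- character()
    if (!("response" %in% assayNames(object)))
        msg <- c(msg, "assay 'response' is required")
    cd <- colData(object)
    if (!("dose" %in% colnames(cd)))
        msg <- c(msg, "colData column 'dose' is required")
    lev <- metadata(object)$doseLevels
    if (is.null(lev) || length(lev) < 1L)
        msg <- c(msg, "metadata doseLevels is required (length >= 1)")
    if (length(msg))
        return(msg)
    if (!is.numeric(cd$dose) || any(!is.finite(cd$dose)))
        msg <- c(msg, "doses must be finite numbers")
    if (is.unsorted(lev, strictly = TRUE))
        msg <- c(msg, "doseLevels must be strictly increasing")
    if (!setequal(unique(cd$dose), lev))
        msg <- c(msg, "doseLevels must equal the set of cell doses")
    y <- assay(object, "response")
    if (!is.numeric(y) || any(!is.finite(y)))
        msg <- c(msg, "all response values must be finite numbers")
    if (length(msg)) msg else TRUE
})

#' PosteriorModel: fitted multinomial-logistic dose posterior
#'
#' A multinomial logistic regression approximation of the dose posterior
#' P(dose | y) under a uniform dose prior, fitted on a subset of the doses of
#' a \linkS4class{DoseResponseExperiment}. The model assumes the log-ratio of
#' posterior probabilities of any dose against the reference (highest
#' selected) dose is linear in the response vector:
#' log P(x_j | y) / P(x_m | y) = alpha_j + beta_j' y. Class-balanced fitting
#' weights enforce the uniform prior, so the maximum-posterior dose coincides
#' with the dose whose conditional response density is largest.
#'
#' @slot doseSubset integer indices (into the experiment's dose levels) the
#'   model was fitted on, ascending.
#' @slot doseLevels numeric dose values of the subset.
#' @slot alpha numeric intercepts, length m'-1 (classes 1..m'-1 against the
#'   reference class m'); length 0 for a single-dose model.
#' @slot beta coefficient matrix, (m'-1) x d.
#' @slot dim response dimension d.
#' @slot featureNames response feature names used at fit time.
#' @slot transform transform metadata copied from the experiment.
#' @slot regularization ridge penalty strength used in fitting.
#'
#' @seealso \code{\link{fitPosteriorModel}}, \code{\link{posteriorProbs}},
#'   \code{\link{assignTypicalDose}}
#' @export
setClass("PosteriorModel",
    representation(
        doseSubset = "integer",
        doseLevels = "numeric",
        alpha = "numeric",
        beta = "matrix",
        dim = "integer",
        featureNames = "character",
        transform = "list",
        regularization = "numeric"
    )
)

setValidity("PosteriorModel", function(object) {
    mprime <- length(object@doseSubset)
    if (mprime < 1L)
        return("doseSubset must be nonempty")
    if (length(object@doseLevels) != mprime)
        return("doseLevels length must match doseSubset")
    if (length(object@alpha) != max(mprime - 1L, 0L))
        return("alpha must have length m' - 1")
    if (mprime > 1L &&
        (nrow(object@beta) != mprime - 1L || ncol(object@beta) != object@dim))
        return("beta must be (m' - 1) x d")
    TRUE
})

#' TypicalFractionMatrix: fractions of cells typical for each dose
#'
#' The m' x m' matrix v with v[i, j] the fraction of cells stimulated with
#' dose i whose responses are typical for dose j, i.e. assigned to dose j by
#' maximum posterior (equivalently, maximum conditional response density under
#' the uniform dose prior). Entries are counts over the n_i cells of dose i,
#' so every row sums to exactly 1.
#'
#' @slot values the m' x m' numeric matrix, dose-labelled dimnames.
#' @slot doseLevels numeric dose values (rows and columns refer to the same
#'   ordered dose subset).
#' @slot counts integer cells per row dose (n_i).
#'
#' @seealso \code{\link{typicalFractionMatrix}},
#'   \code{\link{exactTypicalFractions}}, \code{\link{plotHeterogeneityPies}}
#' @export
setClass("TypicalFractionMatrix",
    representation(
        values = "matrix",
        doseLevels = "numeric",
        counts = "integer"
    )
)

setValidity("TypicalFractionMatrix", function(object) {
    v <- object@values
    m <- length(object@doseLevels)
    if (nrow(v) != m || ncol(v) != m)
        return("values must be m x m with m = length(doseLevels)")
    if (length(object@counts) != m)
        return("counts must have one entry per row dose")
    if (any(v < 0))
        return("fractions must be nonnegative")
    if (any(abs(rowSums(v) - 1) > 1e-6))
        return("every row must sum to 1")
    TRUE
})

#' FRCResult: fractional response curve with heterogeneity structure
#'
#' Holds the per-dose fractional response curve r(x_1)..r(x_m) (the cumulative
#' count of distinct response distributions), its dose-to-dose increments
#' delta r, the all-dose typical-fraction (cell-to-cell heterogeneity) matrix,
#' and optional stratified-bootstrap quantile bands.
#'
#' @slot doseLevels ordered numeric doses.
#' @slot values r(x_i) per dose; r(x_1) = 1 by construction.
#' @slot increments delta r_i = r(x_i) - r(x_{i-1}) (first entry 0).
#' @slot heterogeneity \linkS4class{TypicalFractionMatrix} fitted on all doses.
#' @slot bands list with elements \code{frcLower}, \code{frcUpper},
#'   \code{vLower}, \code{vUpper}, \code{quantiles}, \code{B}, \code{seed},
#'   or empty when no bootstrap was run.
#' @slot settings list of estimation settings (regularization, maxIterations,
#'   crossValidated, transform).
#'
#' @seealso \code{\link{fractionalResponseCurve}}, \code{\link{bootstrapFRA}},
#'   \code{\link{plotFRC}}
#' @export
setClass("FRCResult",
    representation(
        doseLevels = "numeric",
        values = "numeric",
        increments = "numeric",
        heterogeneity = "TypicalFractionMatrix",
        bands = "list",
        settings = "list"
    )
)

setValidity("FRCResult", function(object) {
    m <- length(object@doseLevels)
    if (length(object@values) != m || length(object@increments) != m)
        return("values and increments must have one entry per dose")
    if (abs(object@values[1L] - 1) > 1e-12)
        return("r at the lowest dose must equal 1")
    if (any(object@values < 1 - 1e-9) ||
        any(object@values > seq_len(m) + 1e-9))
        return("r(x_i) must lie in [1, i]")
    TRUE
})

#' ParametricDoseResponseModel: ground-truth per-dose distributions
#'
#' Known parametric response distributions P(Y | dose), one per dose level,
#' each exposing a density and a sampler. Used by the exact-Bayes oracle
#' (\code{\link{exactFRC}}, \code{\link{exactTypicalFractions}}) and paired
#' with sampled datasets by \code{\link{simulateDoseResponse}}.
#'
#' @slot doseLevels ordered numeric doses.
#' @slot distributions list, one element per dose, each a list with
#'   \code{pdf} (vectorized density for d = 1; row-wise density on a matrix
#'   for d > 1), \code{sample} (function(n) drawing from the current RNG
#'   stream), and \code{mean} (numeric length d, for sanity checks).
#' @slot dim response dimension d.
#' @slot support numeric c(lo, hi) integration range for d = 1; for d > 1 an
#'   empty numeric (Monte Carlo integration is used instead).
#'
#' @export
setClass("ParametricDoseResponseModel",
    representation(
        doseLevels = "numeric",
        distributions = "list",
        dim = "integer",
        support = "numeric"
    )
)

setValidity("ParametricDoseResponseModel", function(object) {
    m <- length(object@doseLevels)
    if (length(object@distributions) != m)
        return("one distribution per dose level is required")
    if (is.unsorted(object@doseLevels, strictly = TRUE))
        return("doseLevels must be strictly increasing")
    ok <- vapply(object@distributions, function(dd)
        is.function(dd$pdf) && is.function(dd$sample), logical(1))
    if (!all(ok))
        return("each distribution needs pdf() and sample() functions")
    if (object@dim == 1L && length(object@support) != 2L)
        return("1-D models need a support range c(lo, hi)")
    TRUE
})
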