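#' Simulate single-cell dose-response data with known ground truth
#'
#' Generates a synthetic \linkS4class{DoseResponseExperiment} paired with the
#' \linkS4class{ParametricDoseResponseModel} it was sampled from, in the
#' regimes fractional response analysis is designed for:
#'
#' \describe{
#'   \item{\code{graded}}{IFN-gamma-like univariate responses: per-dose
#'     lognormal whose log-scale location shifts upward with dose
#'     (meanlog = mu0 + s log10(1 + x/K)), so the whole distribution moves
#'     gradually.}
#'   \item{\code{binary}}{IL-10-like on/off responses: a two-component
#'     lognormal mixture whose "on" fraction follows a Hill curve of dose
#'     while the component locations stay fixed — dose mainly changes how
#'     many cells respond, not how much.}
#'   \item{\code{multivariate}}{PBMC-like joint effector responses:
#'     d-dimensional Gaussians whose per-feature means shift
#'     logarithmically with dose, with different half-saturation doses per
#'     feature and exchangeable-correlation noise.}
#'   \item{\code{trajectory}}{NF-kB-like time series: d time points of a
#'     peak-shaped mean curve (peak at tau minutes) whose amplitude
#'     saturates with dose, plus heteroscedastic Gaussian noise,
#'     independent across frames. Each time point is one coordinate of the
#'     response vector; no trajectory-specific features are extracted.}
#'   \item{\code{logdose}}{Weber-Fechner test bed: univariate Gaussian with
#'     mean mu0 + s log10(1 + x/K) and constant sd sigma over log-spaced
#'     doses, so the ground-truth FRC is nearly linear in log10(dose) and
#'     consecutive increments are nearly equal.}
#' }
#'
#' All randomness flows from the single \code{seed}; doses are sampled in
#' ascending order from one stream, so a fixed configuration reproduces a
#' bitwise-identical dataset. The caller's RNG state is left untouched.
#'
#' @param scenario one of \code{"graded"}, \code{"binary"},
#'   \code{"multivariate"}, \code{"trajectory"}, \code{"logdose"}.
#' @param doses dose levels; \code{NULL} for the scenario default.
#' @param cellsPerDose cells sampled per dose (single number or per-dose
#'   vector); \code{NULL} for the scenario default (1000 for the univariate
#'   and multivariate scenarios, 500 for trajectories, 2000 for logdose).
#' @param seed integer RNG seed.
#' @param params named list overriding scenario parameters; see Details.
#' @return list with elements \code{data}
#'   (\linkS4class{DoseResponseExperiment}) and \code{model}
#'   (\linkS4class{ParametricDoseResponseModel}).
#'
#' @details Scenario parameters and defaults:
#' \itemize{
#'   \item graded: \code{mu0 = 1.5}, \code{s = 1}, \code{K = 1},
#'     \code{sdlog = 0.5}; doses 0, 1, 10, 100, 1000.
#'   \item binary: \code{offMeanlog = 1.5}, \code{onMeanlog = 3.5},
#'     \code{offSdlog = onSdlog = 0.5}, Hill \code{ec50 = 10},
#'     \code{hill = 1}; doses 0, 1, 10, 100, 1000.
#'   \item multivariate: \code{d = 5}, \code{s = 1}, per-feature
#'     \code{K = c(5, 10, 25, 50, 100)}, \code{sd = 0.6}, exchangeable
#'     correlation \code{rho = 0.3}; doses 0, 25, 250, 2500.
#'   \item trajectory: \code{d = 21} frames at 3-min spacing over 60 min,
#'     \code{tau = 18}, \code{baseline = 1}, \code{amax = 2},
#'     \code{ec50 = 0.1}, noise \code{sigma0 = 0.1} plus
#'     \code{sigmaRel = 0.2} of the dose-induced mean; doses 0, 0.01, 0.1,
#'     1, 10.
#'   \item logdose: \code{mu0 = 0}, \code{s = 2}, \code{K = 1},
#'     \code{sigma = 1}; doses 10, 1e2, 1e3, 1e4, 1e5 (four decades).
#' }
#' @examples
#' sim <- simulateDoseResponse("graded", cellsPerDose = 100, seed = 1)
#' sim$data
#' exactFRC(sim$model)
#' @export
simulateDoseResponse <- function(scenario = c("graded", "binary",
                                              "multivariate", "trajectory",
                                              "logdose"),
                                 doses = NULL, cellsPerDose = NULL,
                                 seed = 1L, params = list()) {
    scenario <- tryCatch(match.arg(scenario), error = function(e)
        stop("unknown scenario '", scenario[1L], "'; valid scenarios: ",
             "graded, binary, multivariate, trajectory, logdose"))
    p <- utils::modifyList(.scenarioDefaults(scenario), params)
    if (is.null(doses)) doses <- p$doses
    if (is.unsorted(doses, strictly = TRUE))
        stop("doses must be strictly increasing")
    if (is.null(cellsPerDose)) cellsPerDose <- p$cellsPerDose
    n <- rep_len(as.integer(cellsPerDose), length(doses))
    stopifnot(all(n >= 1L))

    model <- switch(scenario,
        graded = lognormalDoseModel(doses,
            meanlogs = p$mu0 + p$s * log10(1 + doses / p$K),
            sdlogs = p$sdlog),
        binary = binaryMixtureDoseModel(doses,
            onFraction = doses^p$hill / (p$ec50^p$hill + doses^p$hill),
            offMeanlog = p$offMeanlog, offSdlog = p$offSdlog,
            onMeanlog = p$onMeanlog, onSdlog = p$onSdlog),
        multivariate = {
            K <- rep_len(p$K, p$d)
            mu <- vapply(seq_len(p$d), function(j)
                p$s * log10(1 + doses / K[j]), numeric(length(doses)))
            mu <- matrix(mu, length(doses), p$d)
            sig <- p$sd^2 * ((1 - p$rho) * diag(p$d) +
                             p$rho * matrix(1, p$d, p$d))
            mvGaussianDoseModel(doses, mu, sig)
        },
        trajectory = {
            tt <- seq(0, p$tmax, length.out = p$d)
            g <- ifelse(tt > 0, (tt / p$tau) * exp(1 - tt / p$tau), 0)
            a <- p$amax * doses / (doses + p$ec50)
            mu <- p$baseline + outer(a, g)
            sd <- p$sigma0 + p$sigmaRel * outer(a, g)
            trajectoryDoseModel(doses, mu, sd)
        },
        logdose = gaussianDoseModel(doses,
            means = p$mu0 + p$s * log10(1 + doses / p$K), sds = p$sigma))

    restore <- .Random.seed_exists()
    on.exit(restore())
    set.seed(seed)
    ys <- vector("list", length(doses))
    for (i in seq_along(doses)) {
        yi <- model@distributions[[i]]$sample(n[i])
        ys[[i]] <- if (is.null(dim(yi))) matrix(yi, ncol = 1L) else yi
    }
    y <- do.call(rbind, ys)
    colnames(y) <- .scenarioFeatureNames(scenario, model@dim, p)
    data <- DoseResponseExperiment(y, rep(doses, n))
    list(data = data, model = model)
}

.scenarioDefaults <- function(scenario) {
    switch(scenario,
        graded = list(doses = c(0, 1, 10, 100, 1000), cellsPerDose = 1000L,
                      mu0 = 1.5, s = 1, K = 1, sdlog = 0.5),
        binary = list(doses = c(0, 1, 10, 100, 1000), cellsPerDose = 1000L,
                      offMeanlog = 1.5, offSdlog = 0.5, onMeanlog = 3.5,
                      onSdlog = 0.5, ec50 = 10, hill = 1),
        multivariate = list(doses = c(0, 25, 250, 2500),
                            cellsPerDose = 1000L, d = 5L, s = 1,
                            K = c(5, 10, 25, 50, 100), sd = 0.6, rho = 0.3),
        trajectory = list(doses = c(0, 0.01, 0.1, 1, 10),
                          cellsPerDose = 500L, d = 21L, tmax = 60,
                          tau = 18, baseline = 1, amax = 2, ec50 = 0.1,
                          sigma0 = 0.1, sigmaRel = 0.2),
        logdose = list(doses = 10^(1:5), cellsPerDose = 2000L, mu0 = 0,
                       s = 2, K = 1, sigma = 1))
}

.scenarioFeatureNames <- function(scenario, d, p) {
    switch(scenario,
        multivariate = paste0("effector", seq_len(d)),
        trajectory = paste0("t", round(seq(0, p$tmax, length.out = d), 1)),
        "response")
}
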