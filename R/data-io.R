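#' Construct a DoseResponseExperiment from per-cell responses and doses
#'
#' Builds the dataset container from a cells-by-features response matrix (or a
#' vector for univariate responses) and a numeric dose per cell. Doses are
#' deduplicated exactly and ordered ascending; cells are stably reordered by
#' dose so that all cells of a dose are contiguous. Rows (cells) containing a
#' non-finite response value are dropped with a warning giving the count (the
#' method has no missing-data model, so imputation is deliberately not
#' offered).
#'
#' @param responses numeric matrix (cells x features) or vector.
#' @param doses numeric vector, one dose per cell; a zero dose (unstimulated
#'   control) is a legal level.
#' @param featureNames optional feature labels (defaults to column names or
#'   \code{y1..yd}).
#' @param doseLabels optional original string labels, one per distinct dose
#'   (in ascending dose order), kept for display.
#' @param transform transform metadata; filled by
#'   \code{\link{transformResponses}}.
#' @return a \linkS4class{DoseResponseExperiment}.
#' @examples
#' dre <- DoseResponseExperiment(
#'     responses = c(rnorm(50), rnorm(50, 3)),
#'     doses = rep(c(0, 10), each = 50))
#' doseLevels(dre)
#' cellsPerDose(dre)
#' @export
DoseResponseExperiment <- function(responses, doses, featureNames = NULL,
                                   doseLabels = NULL,
                                   transform = list(method = "none")) {
    if (is.null(dim(responses)))
        responses <- matrix(as.numeric(responses), ncol = 1L)
    responses <- as.matrix(responses)
    storage.mode(responses) <- "double"
    if (nrow(responses) != length(doses))
        stop("'doses' must have one entry per row of 'responses'")
    if (!is.numeric(doses) || any(!is.finite(doses)))
        stop("doses must be finite numbers")
    if (is.null(featureNames))
        featureNames <- colnames(responses)
    if (is.null(featureNames))
        featureNames <- paste0("y", seq_len(ncol(responses)))

    bad <- !apply(is.finite(responses), 1L, all)
    if (any(bad)) {
        warning(sprintf("dropped %d cell(s) with non-finite response values",
                        sum(bad)))
        responses <- responses[!bad, , drop = FALSE]
        doses <- doses[!bad]
    }
    if (nrow(responses) == 0L)
        stop("no usable cells after dropping non-finite rows")

    lev <- sort(unique(doses))
    idx <- match(doses, lev)
    ord <- order(idx)            # stable: preserves within-dose input order
    responses <- responses[ord, , drop = FALSE]
    doses <- doses[ord]
    idx <- idx[ord]

    if (!is.null(doseLabels) && length(doseLabels) != length(lev))
        stop("doseLabels must have one entry per distinct dose")

    assay <- t(responses)
    rownames(assay) <- featureNames
    colnames(assay) <- sprintf("cell%d", seq_len(ncol(assay)))
    se <- SummarizedExperiment(
        assays = list(response = assay),
        colData = S4Vectors::DataFrame(dose = doses, doseIndex = idx,
                                       row.names = colnames(assay)))
    metadata(se)$doseLevels <- lev
    metadata(se)$doseLabels <- if (is.null(doseLabels))
        format(lev, trim = TRUE) else doseLabels
    metadata(se)$transform <- transform
    new("DoseResponseExperiment", se)
}

#' Read a delimited single-cell dose-response table
#'
#' Reads a delimited text file with one header row and one row per cell: a
#' numeric dose column and one or more numeric response columns. Doses are
#' sorted ascending with stable reindexing of cells; rows with non-finite
#' responses are dropped with a warning. Replicate files for the same dose can
#' simply be concatenated before reading: doses are keyed by numeric value and
#' pooled.
#'
#' @param path file path.
#' @param doseColumn name of the dose column (default \code{"dose"}).
#' @param responseColumns character vector of response column names, or
#'   \code{NULL} to use all non-dose columns.
#' @param delimiter field separator (default comma).
#' @return a \linkS4class{DoseResponseExperiment}.
#' @seealso \code{\link{writeDoseResponse}} for the inverse.
#' @export
readDoseResponse <- function(path, doseColumn = "dose",
                             responseColumns = NULL, delimiter = ",") {
    if (!file.exists(path))
        stop("file not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (!(doseColumn %in% names(tab)))
        stop("dose column '", doseColumn, "' not found in ", path)
    if (is.null(responseColumns))
        responseColumns <- setdiff(names(tab), doseColumn)
    missing <- setdiff(responseColumns, names(tab))
    if (length(missing))
        stop("response column(s) not found: ", paste(missing, collapse = ", "))
    if (length(responseColumns) == 0L)
        stop("at least one response column is required")

    rawDose <- tab[[doseColumn]]
    doses <- suppressWarnings(as.numeric(rawDose))
    if (any(is.na(doses))) {
        bad <- which(is.na(doses))[1L]
        stop(sprintf("non-numeric dose value '%s' at data row %d",
                     as.character(rawDose[bad]), bad))
    }
    resp <- as.matrix(tab[responseColumns])
    suppressWarnings(storage.mode(resp) <- "double")
    resp[is.na(resp)] <- NaN      # uniform non-finite marker for row dropping
    usable <- apply(is.finite(resp), 1L, all)
    gone <- setdiff(unique(doses), unique(doses[usable]))
    if (length(gone))
        stop("no usable rows for dose ", paste(gone, collapse = ", "))
    DoseResponseExperiment(resp, doses, featureNames = responseColumns)
}

#' Write a DoseResponseExperiment back to delimited text
#'
#' Serializes to the same dialect \code{\link{readDoseResponse}} reads: a
#' \code{dose} column followed by the response features, one row per cell.
#' A read/write round trip reproduces doses, counts, and responses at the
#' written precision (15 significant digits).
#'
#' @param x a \linkS4class{DoseResponseExperiment}.
#' @param path output file path.
#' @param delimiter field separator.
#' @return \code{path}, invisibly.
#' @export
writeDoseResponse <- function(x, path, delimiter = ",") {
    df <- data.frame(dose = colData(x)$dose,
                     signif(responses(x), 15), check.names = FALSE)
    names(df) <- c("dose", rownames(x))
    utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @describeIn DoseResponseExperiment ordered distinct dose values.
#' @param x a \linkS4class{DoseResponseExperiment}.
#' @name doseLevels
#' @export
setMethod("doseLevels", "DoseResponseExperiment",
    function(x) metadata(x)$doseLevels)

#' Per-cell dose index
#'
#' Integer index of each cell's dose into \code{doseLevels(x)}.
#' @param x a \linkS4class{DoseResponseExperiment}.
#' @name doseIndex
#' @export
setMethod("doseIndex", "DoseResponseExperiment",
    function(x) colData(x)$doseIndex)

#' Number of cells measured at each dose
#'
#' @param x a \linkS4class{DoseResponseExperiment}.
#' @return named integer vector n_1..n_m.
#' @name cellsPerDose
#' @export
setMethod("cellsPerDose", "DoseResponseExperiment", function(x) {
    n <- tabulate(doseIndex(x), nbins = length(doseLevels(x)))
    names(n) <- metadata(x)$doseLabels
    n
})

#' Per-cell response matrix
#'
#' @param x a \linkS4class{DoseResponseExperiment}.
#' @return numeric matrix, cells x features.
#' @name responses
#' @export
setMethod("responses", "DoseResponseExperiment",
    function(x) t(assay(x, "response")))

#' Apply a standard response transform
#'
#' Applies an elementwise variance-stabilizing transform to all response
#' features; doses are untouched and the transform is recorded in the dataset
#' metadata. \code{arcsinh} with cofactor 5 is the customary choice for mass
#' cytometry, \code{log1p} for fluorescence intensities; the default is no
#' transform, and because classification results depend on the choice it is
#' always recorded explicitly.
#'
#' @param x a \linkS4class{DoseResponseExperiment}.
#' @param method one of \code{"none"}, \code{"log1p"}, \code{"arcsinh"}.
#' @param cofactor positive scale for \code{arcsinh(y / cofactor)}.
#' @return the transformed \linkS4class{DoseResponseExperiment}.
#' @name transformResponses
#' @export
setMethod("transformResponses", "DoseResponseExperiment",
    function(x, method = c("none", "log1p", "arcsinh"), cofactor = 5) {
        method <- match.arg(method)
        y <- assay(x, "response")
        y2 <- switch(method,
            none = y,
            log1p = log1p(y),
            arcsinh = {
                if (!is.numeric(cofactor) || length(cofactor) != 1L ||
                    cofactor <= 0)
                    stop("cofactor must be a positive number")
                asinh(y / cofactor)
            })
        if (any(!is.finite(y2)))
            stop("internal error: transform produced non-finite values")
        assay(x, "response") <- y2
        metadata(x)$transform <- list(method = method,
            cofactor = if (method == "arcsinh") cofactor else NULL)
        validObject(x)
        x
    })

#' Check a dataset's adequacy for fractional response analysis
#'
#' Returns (never raises) a character vector of warnings about conditions
#' under which the classifier-based estimates are unreliable: the number of
#' cells per dose should considerably exceed the response dimension (by
#' default a factor of 10), at least two doses are needed for a non-trivial
#' curve, and very small per-dose samples make the estimated fractions noisy.
#'
#' @param x a \linkS4class{DoseResponseExperiment}.
#' @param minCellsPerFeature required cells-per-dose per response dimension
#'   (default 10).
#' @return character vector of warnings; empty when the dataset looks fine.
#' @export
validateForFRA <- function(x, minCellsPerFeature = 10) {
    w <- character()
    m <- length(doseLevels(x))
    d <- nrow(x)
    n <- cellsPerDose(x)
    if (m < 2L)
        w <- c(w, "single dose: FRC is identically 1")
    need <- minCellsPerFeature * d
    low <- which(n < need)
    for (i in low)
        w <- c(w, sprintf(
            "dose %s: %d cells < %d (%g cells per response dimension, d = %d)",
            metadata(x)$doseLabels[i], n[i], need, minCellsPerFeature, d))
    tiny <- which(n < 25L)
    for (i in tiny)
        w <- c(w, sprintf("dose %s: fewer than 25 cells",
                          metadata(x)$doseLabels[i]))
    w
}

#' @describeIn DoseResponseExperiment compact display.
#' @param object a \linkS4class{DoseResponseExperiment}.
#' @export
setMethod("show", "DoseResponseExperiment", function(object) {
    cat("DoseResponseExperiment:", ncol(object), "cells,",
        nrow(object), "response feature(s),",
        length(doseLevels(object)), "dose level(s)\n")
    cat("  doses:", paste(metadata(object)$doseLabels, collapse = ", "), "\n")
    cat("  cells per dose:", paste(cellsPerDose(object), collapse = ", "),
        "\n")
    tr <- metadata(object)$transform
    cat("  transform:", tr$method,
        if (!is.null(tr$cofactor)) sprintf("(cofactor %g)", tr$cofactor)
        else "", "\n")
})
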