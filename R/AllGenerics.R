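#' @rdname doseLevels
#' @export
setGeneric("doseLevels", function(x) standardGeneric("doseLevels"))

#' @rdname doseIndex
#' @export
setGeneric("doseIndex", function(x) standardGeneric("doseIndex"))

#' @rdname cellsPerDose
#' @export
setGeneric("cellsPerDose", function(x) standardGeneric("cellsPerDose"))

#' @rdname responses
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname transformResponses
#' @export
setGeneric("transformResponses",
    function(x, method = c("none", "log1p", "arcsinh"), cofactor = 5)
        standardGeneric("transformResponses"))

#' @rdname frcValues
#' @export
setGeneric("frcValues", function(x) standardGeneric("frcValues"))

#' @rdname frcIncrements
#' @export
setGeneric("frcIncrements", function(x) standardGeneric("frcIncrements"))

#' @rdname heterogeneity
#' @export
setGeneric("heterogeneity", function(x) standardGeneric("heterogeneity"))

#' @rdname bootstrapBands
#' @export
setGeneric("bootstrapBands", function(x) standardGeneric("bootstrapBands"))

#' @rdname fractionValues
#' @export
setGeneric("fractionValues", function(x) standardGeneric("fractionValues"))
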