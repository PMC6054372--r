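#' @include utils.R
NULL

#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @export
setGeneric("handleContour", function(x) standardGeneric("handleContour"))

#' @export
setGeneric("foldedContour", function(x) standardGeneric("foldedContour"))

#' @export
setGeneric("releasableContour", function(x) standardGeneric("releasableContour"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @export
setGeneric("unfoldingLength", function(x) standardGeneric("unfoldingLength"))

#' @export
setGeneric("isAccepted", function(x) standardGeneric("isAccepted"))

#' @export
setGeneric("peakForces", function(x) standardGeneric("peakForces"))

#' @export
setGeneric("cellMeanForce", function(x) standardGeneric("cellMeanForce"))

#' @export
setGeneric("immobileFraction", function(x) standardGeneric("immobileFraction"))

#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
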