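#' @include AllClasses.R
NULL

#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @export
setGeneric("trajectoryData", function(x) standardGeneric("trajectoryData"))

#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

#' @export
setGeneric("lagTimes", function(x) standardGeneric("lagTimes"))

#' @export
setGeneric("msdValues", function(x) standardGeneric("msdValues"))

#' @export
setGeneric("intervalCounts", function(x) standardGeneric("intervalCounts"))

#' @export
setGeneric("curveLevel", function(x) standardGeneric("curveLevel"))

#' @export
setGeneric("alphaExponent", function(x) standardGeneric("alphaExponent"))

#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setGeneric("significanceCode", function(x) standardGeneric("significanceCode"))

#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
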