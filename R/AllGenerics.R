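#' @rdname indicatorValues
#' @export
setGeneric("indicatorValues", function(x, ...) standardGeneric("indicatorValues"))

#' @rdname indicatorValues
#' @export
setGeneric("indicatorSds", function(x, ...) standardGeneric("indicatorSds"))

#' @rdname indicatorValues
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))

#' @rdname indicatorValues
#' @export
setGeneric("indicatorNames", function(x) standardGeneric("indicatorNames"))

#' @rdname indicatorValues
#' @export
setGeneric("indicatorOrientation", function(x) standardGeneric("indicatorOrientation"))

#' @rdname entropyWeights
#' @export
setGeneric("entropyWeights", function(x, ...) standardGeneric("entropyWeights"))

#' @rdname topsisScores
#' @export
setGeneric("topsisScores", function(x, weights, ...) standardGeneric("topsisScores"))

#' @rdname rankStrains
#' @export
setGeneric("rankStrains", function(x, ...) standardGeneric("rankStrains"))

#' @rdname pcaProject
#' @export
setGeneric("pcaProject", function(x, ...) standardGeneric("pcaProject"))

#' @rdname columnSummary
#' @export
setGeneric("columnSummary", function(x, indicator, stat = c("min", "max", "range"))
  standardGeneric("columnSummary"))

#' @rdname shiftPositive
#' @export
setGeneric("shiftPositive", function(x, epsilon = 1e-6) standardGeneric("shiftPositive"))
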