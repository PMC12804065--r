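#' @rdname ItemBank-class
#' @param x an object.
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname ItemBank-class
#' @export
setGeneric("difficulty", function(x) standardGeneric("difficulty"))

#' @rdname ItemBank-class
#' @export
setGeneric("timeIntensity", function(x) standardGeneric("timeIntensity"))

#' @rdname ThresholdSet-class
#' @param x an object.
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname ResponseExperiment-class
#' @param x an object.
#' @export
setGeneric("responseMatrix", function(x) standardGeneric("responseMatrix"))

#' @rdname ResponseExperiment-class
#' @export
setGeneric("timeMatrix", function(x) standardGeneric("timeMatrix"))

#' @rdname ResponseExperiment-class
#' @export
setGeneric("engagementMatrix", function(x) standardGeneric("engagementMatrix"))

#' @rdname ResponseExperiment-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname RaschFit-class
#' @param x an object.
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname RaschFit-class
#' @export
setGeneric("logLikTrace", function(x) standardGeneric("logLikTrace"))

#' @rdname PlausibleValues-class
#' @param x an object.
#' @export
setGeneric("pvMatrix", function(x) standardGeneric("pvMatrix"))

#' @rdname PlausibleValues-class
#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))
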