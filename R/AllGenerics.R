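#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family for the package's S4 containers; see the class
#' pages for details.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("electrodeCount", function(x) standardGeneric("electrodeCount"))

#' @rdname accessors
#' @export
setGeneric("lfpSamples", function(x) standardGeneric("lfpSamples"))

#' @rdname accessors
#' @export
setGeneric("sessionEvents", function(x) standardGeneric("sessionEvents"))

#' @rdname accessors
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))

#' @rdname accessors
#' @export
setGeneric("percentCorrect", function(x) standardGeneric("percentCorrect"))

#' @rdname accessors
#' @export
setGeneric("learningStage", function(x) standardGeneric("learningStage"))

#' @rdname accessors
#' @export
setGeneric("miValue", function(x) standardGeneric("miValue"))

#' @rdname accessors
#' @export
setGeneric("peakPhase", function(x) standardGeneric("peakPhase"))

#' @rdname accessors
#' @export
setGeneric("troughPhase", function(x) standardGeneric("troughPhase"))

#' @rdname accessors
#' @export
setGeneric("phaseDistribution", function(x) standardGeneric("phaseDistribution"))

#' @rdname accessors
#' @export
setGeneric("prpValues", function(x) standardGeneric("prpValues"))

#' @rdname accessors
#' @export
setGeneric("timeBins", function(x) standardGeneric("timeBins"))

#' @rdname accessors
#' @export
setGeneric("decodingAccuracy", function(x) standardGeneric("decodingAccuracy"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("dimCurves", function(x) standardGeneric("dimCurves"))

#' @rdname accessors
#' @export
setGeneric("ciBounds", function(x) standardGeneric("ciBounds"))
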