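#' Accessors for scmetal S4 objects
#'
#' `times()`, `intensities()`, `dwellTime()`, `analyte()` and
#' `acquisitionId()` read the slots of a [TimeTrace-class];
#' `thresholdValue()` the CPS level of a [Threshold-class];
#' `calSlope()`, `calIntercept()` and `calRSquared()` the coefficients of a
#' [CalibrationCurve-class].
#'
#' @param x the object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("times", function(x) standardGeneric("times"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("dwellTime", function(x) standardGeneric("dwellTime"))
#' @rdname accessors
#' @export
setGeneric("analyte", function(x) standardGeneric("analyte"))
#' @rdname accessors
#' @export
setGeneric("acquisitionId", function(x) standardGeneric("acquisitionId"))
#' @rdname accessors
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))
#' @rdname accessors
#' @export
setGeneric("calSlope", function(x) standardGeneric("calSlope"))
#' @rdname accessors
#' @export
setGeneric("calIntercept", function(x) standardGeneric("calIntercept"))
#' @rdname accessors
#' @export
setGeneric("calRSquared", function(x) standardGeneric("calRSquared"))

#' @rdname accessors
setMethod("times", "TimeTrace", function(x) x@times)
#' @rdname accessors
setMethod("intensities", "TimeTrace", function(x) x@intensities)
#' @rdname accessors
setMethod("dwellTime", "TimeTrace", function(x) x@dwellTime)
#' @rdname accessors
setMethod("analyte", "TimeTrace", function(x) x@analyte)
#' @rdname accessors
setMethod("acquisitionId", "TimeTrace", function(x) x@acquisitionId)
#' @rdname accessors
setMethod("thresholdValue", "Threshold", function(x) x@value)
#' @rdname accessors
setMethod("calSlope", "CalibrationCurve", function(x) x@slope)
#' @rdname accessors
setMethod("calIntercept", "CalibrationCurve", function(x) x@intercept)
#' @rdname accessors
setMethod("calRSquared", "CalibrationCurve", function(x) x@rSquared)
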