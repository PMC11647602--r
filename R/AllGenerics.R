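#' @include AllClasses.R
NULL

#' Accessors for secmam classes
#'
#' Slot access goes through these accessors; the slot layout is not part of
#' the API.
#'
#' @param object a secmam object.
#' @param x a secmam object.
#' @param channel character(1) channel name.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("getTrace", function(object, channel) standardGeneric("getTrace"))

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))

#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("delayOffset", function(object) standardGeneric("delayOffset"))

#' @rdname accessors
#' @export
setGeneric("dilutionFactor", function(object) standardGeneric("dilutionFactor"))

#' @rdname accessors
#' @export
setGeneric("injectionVolume", function(object) standardGeneric("injectionVolume"))

#' @rdname accessors
#' @export
setGeneric("temperatureLabel", function(object) standardGeneric("temperatureLabel"))

#' @rdname accessors
#' @export
setGeneric("runMetadata", function(object) standardGeneric("runMetadata"))

#' @rdname accessors
#' @export
setGeneric("scatteringAngles", function(object) standardGeneric("scatteringAngles"))

#' @rdname accessors
#' @export
setGeneric("peakData", function(object) standardGeneric("peakData"))

#' @rdname accessors
#' @export
setGeneric("peakAreas", function(object) standardGeneric("peakAreas"))

#' @rdname accessors
#' @export
setGeneric("percentAreas", function(object) standardGeneric("percentAreas"))

#' @rdname accessors
#' @export
setGeneric("totalAreas", function(object) standardGeneric("totalAreas"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("residualSd", function(object) standardGeneric("residualSd"))

#' @rdname accessors
#' @export
setGeneric("lod", function(object) standardGeneric("lod"))

#' @rdname accessors
#' @export
setGeneric("loq", function(object) standardGeneric("loq"))

setMethod("sampleId", "Chromatogram", function(object) object@sampleId)
setMethod("channelNames", "Chromatogram", function(object) names(object@traces))
setMethod("getTrace", "Chromatogram", function(object, channel) {
  if (!channel %in% names(object@traces))
    stop("chromatogram '", object@sampleId, "' has no channel ", channel)
  object@traces[[channel]]
})
setMethod("traceTimes", "Trace", function(object) object@times)
setMethod("traceValues", "Trace", function(object) object@values)
setMethod("delayOffset", "Trace", function(object) object@delayOffset)
setMethod("dilutionFactor", "Chromatogram", function(object) object@dilutionFactor)
setMethod("injectionVolume", "Chromatogram", function(object) object@injectionVolume)
setMethod("temperatureLabel", "Chromatogram", function(object) object@temperature)
setMethod("runMetadata", "Chromatogram", function(object) object@metadata)
setMethod("scatteringAngles", "Chromatogram", function(object) object@angles)

setMethod("peakData", "PeakTable", function(object) {
  cbind(object@peaks,
        as.data.frame(object@areas,
                      col.names = paste0("area_", colnames(object@areas))))
})
setMethod("peakAreas", "PeakTable", function(object) object@areas)
setMethod("percentAreas", "PeakTable", function(object) object@percentArea)
setMethod("totalAreas", "PeakTable", function(object) object@totalArea)

setMethod("rSquared", "CalibrationCurve", function(object) object@rSquared)
setMethod("residualSd", "CalibrationCurve", function(object) object@residualSd)
setMethod("lod", "CalibrationCurve", function(object) object@lod)
setMethod("loq", "CalibrationCurve", function(object) object@loq)

#' @rdname accessors
#' @param ... ignored.
#' @export
coef.CalibrationCurve <- function(object, ...)
  c(intercept = object@intercept, slope = object@slope)
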