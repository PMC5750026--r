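# Generics and accessor/show methods. Slot access from user code goes
# through these accessors, never through @.

#' @rdname AudioRecording
#' @param object,x an object.
#' @export
setGeneric("audioSamples", function(object) standardGeneric("audioSamples"))

#' @rdname AudioRecording
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname AudioRecording
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @rdname AudioRecording
#' @export
setMethod("audioSamples", "AudioRecording", function(object) object@samples)

#' @rdname AudioRecording
#' @export
setMethod("sampleRate", "AudioRecording", function(object) object@sampleRate)

#' @rdname AudioRecording
#' @export
setMethod("duration", "AudioRecording",
          function(object) length(object@samples) / object@sampleRate)

setMethod("show", "AudioRecording", function(object) {
  cat(sprintf("AudioRecording: %d samples @ %g Hz (%.2f s, start %.2f s)\n",
              length(object@samples), object@sampleRate, duration(object),
              object@startTime))
})

#' @rdname BeatEvents
#' @param object,x a `BeatEvents` object.
#' @export
setGeneric("beatTimes", function(object) standardGeneric("beatTimes"))

#' @rdname BeatEvents
#' @export
setGeneric("windowCounts", function(object) standardGeneric("windowCounts"))

#' @rdname BeatEvents
#' @export
setMethod("beatTimes", "BeatEvents", function(object) object@eventTimes)

#' @rdname BeatEvents
#' @export
setMethod("windowCounts", "BeatEvents", function(object) object@windowCounts)

setMethod("show", "BeatEvents", function(object) {
  cat(sprintf(
    "BeatEvents: %d events over %d windows (%g samples each, %.1f windows/s)%s\n",
    length(object@eventTimes), length(object@windowCounts),
    object@windowLen, object@sampleRate / object@windowLen,
    if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ", "), "]")
    else ""))
})

setMethod("show", "HeartRateSeries", function(object) {
  ok <- object@quality != "filtered-out" & !is.na(object@bpm)
  cat(sprintf("HeartRateSeries: %d values (%d usable), %.1f-%.1f bpm\n",
              length(object@bpm), sum(ok),
              if (any(ok)) min(object@bpm[ok]) else NA,
              if (any(ok)) max(object@bpm[ok]) else NA))
})

#' @rdname HeartRateSeries
#' @param x a `HeartRateSeries`.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
as.data.frame.HeartRateSeries <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(time = x@time, bpm = x@bpm, quality = x@quality)
}

setMethod("show", "RespirometryTrace", function(object) {
  cat(sprintf(
    "RespirometryTrace: %d samples over %.1f min, flow %g ml/min%s%s\n",
    length(object@time), diff(range(object@time)) / 60,
    object@flowRate[1L],
    sprintf(", %d baseline samples", sum(object@baselineMask)),
    if (object@corrected) " (baseline-corrected)" else ""))
})

#' @rdname RespirometryTrace
#' @param x a `RespirometryTrace`.
#' @param row.names,optional,... conventional; unused.
#' @export
as.data.frame.RespirometryTrace <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(time = x@time, feco2 = x@feco2, fico2 = x@fico2,
             feo2 = x@feo2, fio2 = x@fio2, flow_rate = x@flowRate,
             chamber_temp = x@chamberTemp, rh = x@rh,
             baseline = x@baselineMask)
}

setMethod("show", "MetabolicSeries", function(object) {
  cat(sprintf(
    "MetabolicSeries: %d samples, MR %.3f-%.3f kJ/h (mass %.1f g)\n",
    length(object@time), min(object@mrKjH), max(object@mrKjH),
    object@massG))
})

#' @rdname MetabolicSeries
#' @param x a `MetabolicSeries`.
#' @param row.names,optional,... conventional; unused.
#' @export
as.data.frame.MetabolicSeries <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(time = x@time, vco2 = x@vco2, vo2 = x@vo2,
             mr_kj_h = x@mrKjH, mr_w_g = x@mrWg)
}

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit (%s): %s\n", object@fitMethod, object@formula))
  cat("  beta:", paste(sprintf("%s=%.4g", names(object@beta), object@beta),
                       collapse = ", "), "\n")
  cat(sprintf("  sigma_u=%.4g sigma_e=%.4g logLik=%.2f n=%d k=%d\n",
              object@sigmaU, object@sigmaE, object@loglik,
              as.integer(object@nObs), as.integer(object@kParams)))
  cat(sprintf("  AICc=%.2f R2m=%.3f R2c=%.3f%s\n", object@aicc,
              object@r2m, object@r2c,
              if (object@singular) " [singular fit]" else ""))
})

setMethod("show", "MixedModelSpec", function(object) {
  cat(sprintf(
    "MixedModelSpec: %s = %.4g + %.4g * %s + u_i + e; sd_u=%g sd_e=%g (%s)\n",
    object@response, object@intercept, object@slope, object@predictor,
    object@sigmaIndividual, object@sigmaResidual, object@unit))
  cat(sprintf("  %d individuals x %d obs, %s in [%g, %g]\n",
              as.integer(object@nIndividuals),
              as.integer(object@nObsPerIndividual), object@predictor,
              object@xRange[1L], object@xRange[2L]))
})
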