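#' @name accessors
#' @title Accessors for crosssort classes
#' @description Slot access for the S4 containers; user code should use these
#'   rather than `@`.
#' @param x an object of the documented class.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))
#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("embeddingPoints", function(x) standardGeneric("embeddingPoints"))
#' @rdname accessors
#' @export
setGeneric("embeddingTimes", function(x) standardGeneric("embeddingTimes"))
#' @rdname accessors
#' @export
setGeneric("embeddingParams", function(x) standardGeneric("embeddingParams"))
#' @rdname accessors
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))
#' @rdname accessors
#' @export
setGeneric("embeddingLag", function(x) standardGeneric("embeddingLag"))
#' @rdname accessors
#' @export
setGeneric("scoreValue", function(x) standardGeneric("scoreValue"))
#' @rdname accessors
#' @export
setGeneric("scoreMethod", function(x) standardGeneric("scoreMethod"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("fitOk", function(x) standardGeneric("fitOk"))
#' @rdname accessors
#' @export
setGeneric("couplingMatrix", function(x) standardGeneric("couplingMatrix"))
#' @rdname accessors
#' @export
setGeneric("truthMatrix", function(x) standardGeneric("truthMatrix"))
#' @rdname accessors
#' @export
setGeneric("trialSeries", function(x) standardGeneric("trialSeries"))
#' @rdname accessors
#' @export
setGeneric("networkSpec", function(x) standardGeneric("networkSpec"))
#' @rdname accessors
#' @export
setGeneric("windowScores", function(x) standardGeneric("windowScores"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

setMethod("tsValues", "TimeSeries", function(x) x@values)
setMethod("samplingInterval", "TimeSeries", function(x) x@dt)
setMethod("channelNames", "TimeSeries", function(x) x@labels)
setMethod("nSamples", "TimeSeries", function(x) nrow(x@values))
setMethod("nChannels", "TimeSeries", function(x) ncol(x@values))

setMethod("embeddingPoints", "DelayEmbedding", function(x) x@points)
setMethod("embeddingTimes", "DelayEmbedding", function(x) x@times)
setMethod("embeddingParams", "DelayEmbedding", function(x) x@params)
setMethod("embeddingDim", "EmbeddingParams", function(x) x@embDim)
setMethod("embeddingLag", "EmbeddingParams", function(x) x@embLag)
setMethod("embeddingDim", "DelayEmbedding", function(x) x@params@embDim)
setMethod("embeddingLag", "DelayEmbedding", function(x) x@params@embLag)

setMethod("scoreValue", "CouplingScore", function(x) x@value)
setMethod("scoreMethod", "CouplingScore", function(x) x@method)
setMethod("pValue", "CouplingScore", function(x) x@pValue)
setMethod("fitOk", "CouplingScore", function(x) x@fitOk)

setMethod("couplingMatrix", "NetworkSpec", function(x) x@coupling)
setMethod("couplingMatrix", "TrialResult", function(x) x@spec@coupling)
setMethod("truthMatrix", "TrialResult", function(x) x@truth)
setMethod("trialSeries", "TrialResult", function(x) x@series)
setMethod("networkSpec", "TrialResult", function(x) x@spec)

setMethod("windowScores", "WindowedScores", function(x) x@scores)
setMethod("epochLabels", "WindowedScores", function(x) x@epochLabels)
setMethod("stateLabels", "StateSequences", function(x) x@labels)
setMethod("epochLabels", "StateSequences", function(x) x@epochLabels)

setMethod("show", "TimeSeries", function(object) {
  cat(sprintf("TimeSeries: %d samples x %d channel(s), dt = %g\n",
              nSamples(object), nChannels(object), object@dt))
  cat("  channels:", paste(object@labels, collapse = ", "), "\n")
})

setMethod("show", "DelayEmbedding", function(object) {
  cat(sprintf("DelayEmbedding: %d points in dimension %d (lag %d)\n",
              nrow(object@points), object@params@embDim, object@params@embLag))
})

setMethod("show", "CouplingScore", function(object) {
  cat(sprintf("%s score(%s -> %s) = %.4f%s%s\n", object@method,
              object@source, object@target, object@value,
              if (!object@fitOk) " [linear fallback]" else "",
              if (!is.na(object@pValue))
                sprintf(", p = %.3g", object@pValue) else ""))
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec '%s': %s system, %d variables\n",
              object@topologyTag, object@system, object@nVars))
  print(object@coupling)
})

setMethod("show", "TrialResult", function(object) {
  cat(sprintf("TrialResult: %s '%s', L = %d, snr = %g dB, eps = %g\n",
              object@spec@system, object@spec@topologyTag,
              nSamples(object@series), object@noise@snrDb,
              object@noise@dynEps))
})

setMethod("show", "WindowedScores", function(object) {
  d <- dim(object@scores)
  cat(sprintf(
    "WindowedScores: %d epoch(s) x %d window(s) x %d directed pairs\n",
    d[1], d[2], d[3]))
  cat("  pairs:", paste(object@pairNames, collapse = ", "), "\n")
})

setMethod("show", "StateSequences", function(object) {
  cat(sprintf("StateSequences: %d epoch(s) x %d window(s), k = %d states\n",
              nrow(object@labels), ncol(object@labels), object@k))
})
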