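## Generics and accessors. Slot access from user code should go through
## these rather than `@`.

#' @name accessors
#' @title Accessors for pipeline objects
#' @description Small accessor generics exposing the slots of the pipeline
#'   classes without direct slot access.
#' @param object an object of the documented class.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setMethod("signalData", "RawRecording", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "RawRecording", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "RawRecording", function(object) object@channelNames)

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setMethod("nChannels", "RawRecording", function(object) ncol(object@data))
#' @rdname accessors
#' @export
setMethod("nChannels", "SimConfig", function(object) object@nChannels)

#' @rdname accessors
#' @export
setGeneric("recording", function(object) standardGeneric("recording"))
#' @rdname accessors
#' @export
setMethod("recording", "SimulatedTrial", function(object) object@recording)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "SimulatedTrial", function(object) object@groundTruth)

#' @rdname accessors
#' @export
setGeneric("simulationConfig",
           function(object) standardGeneric("simulationConfig"))
#' @rdname accessors
#' @export
setMethod("simulationConfig", "SimulatedTrial",
          function(object) object@config)

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("windowTimes", function(object) standardGeneric("windowTimes"))
#' @rdname accessors
#' @export
setMethod("windowTimes", "FeatureMatrix", function(object) object@windowTimes)

#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(object) standardGeneric("basisMatrix"))
#' @rdname accessors
#' @export
setMethod("basisMatrix", "SynergyResult", function(object) object@W)

#' @rdname accessors
#' @export
setGeneric("coefMatrix", function(object) standardGeneric("coefMatrix"))
#' @rdname accessors
#' @export
setMethod("coefMatrix", "SynergyResult", function(object) object@H)

#' @rdname accessors
#' @export
setGeneric("vafByK", function(object) standardGeneric("vafByK"))
#' @rdname accessors
#' @export
setMethod("vafByK", "SynergyResult", function(object) object@vafByK)

#' @rdname accessors
#' @export
setGeneric("kSelected", function(object) standardGeneric("kSelected"))
#' @rdname accessors
#' @export
setMethod("kSelected", "SynergyResult", function(object) object@kSelected)

#' @rdname accessors
#' @export
setGeneric("contributions", function(object) standardGeneric("contributions"))
#' @rdname accessors
#' @export
setMethod("contributions", "SynergyResult",
          function(object) object@contributions)

#' @rdname accessors
#' @export
setGeneric("channelsSelected",
           function(object) standardGeneric("channelsSelected"))
#' @rdname accessors
#' @export
setMethod("channelsSelected", "SynergyResult",
          function(object) object@channelsSelected)

#' @rdname accessors
#' @export
setGeneric("sequences", function(object) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setMethod("sequences", "LabeledDataset", function(object) object@sequences)

#' @rdname accessors
#' @export
setGeneric("labels2", function(object) standardGeneric("labels2"))
#' @rdname accessors
#' @export
setMethod("labels2", "LabeledDataset", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("groups", function(object) standardGeneric("groups"))
#' @rdname accessors
#' @export
setMethod("groups", "LabeledDataset", function(object) object@groups)

#' Predict class probabilities
#'
#' @param object a trained classifier (Transformer, LSTM or boosted-tree
#'   model returned by the training functions).
#' @param newdata a \linkS4class{LabeledDataset} or list of sequence
#'   matrices.
#' @param ... unused.
#' @return a list with \code{prob} (n x 2 matrix, columns relaxed /
#'   fatigued, rows summing to 1) and \code{label} (hard 0/1 labels by
#'   argmax, threshold 0.5 on the fatigued column).
#' @export
setGeneric("predictProb",
           function(object, newdata, ...) standardGeneric("predictProb"))

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording: %d samples x %d channels at %g Hz (%.2f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              nrow(object@data) / object@fs))
  cat("channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d ch at %g Hz, %.1f s, %d synergies, %g reps/min\n",
    object@nChannels, object@fs, object@duration, object@nSynergies,
    object@cycleRate))
  cat(sprintf("  fatigue: gain %.2f -> %.2f, carrier MF %g -> %g Hz, noise %.3f\n",
              object@gainStart, object@gainEnd, object@mfStart, object@mfEnd,
              object@noiseFloor))
  cat(sprintf("  dominant channels: %s; seed %d\n",
              paste(object@dominantChannels, collapse = ","), object@seed))
})

setMethod("show", "SimulatedTrial", function(object) {
  cat("SimulatedTrial\n")
  show(object@recording)
  b <- object@groundTruth@labelBoundaries
  cat(sprintf("  relaxed: [%.1f, %.1f] s; fatigued: [%.1f, %.1f] s\n",
              b$relaxed[1], b$relaxed[2], b$fatigued[1], b$fatigued[2]))
})

setMethod("show", "SynergyResult", function(object) {
  cat(sprintf("SynergyResult: k = %d selected\n", object@kSelected))
  v <- object@vafByK
  cat("  VAF by k:", paste(sprintf("%d:%.3f", v$k, v$mean), collapse = " "),
      "\n")
  cat("  channels selected:",
      paste(object@channelsSelected, collapse = ", "), "\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d windows x %d features (channel %d)\n",
              nrow(object@values), ncol(object@values), object@channel))
  cat("  features:", paste(colnames(object@values), collapse = ", "), "\n")
})

setMethod("show", "LabeledDataset", function(object) {
  n <- length(object@sequences)
  d <- if (n) dim(object@sequences[[1]]) else c(0L, 0L)
  cat(sprintf(
    "LabeledDataset: %d sequences [%d x %d], %d relaxed / %d fatigued\n",
    n, d[1], d[2], sum(object@labels == 0L), sum(object@labels == 1L)))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n  counts:",
      paste(names(object@counts), object@counts, sep = "=", collapse = " "),
      "\n")
  m <- object@metrics
  cat("  metrics:",
      paste(sprintf("%s=%.4f", m$metric, m$mean), collapse = " "), "\n")
  cat(sprintf("  AUC: %.4f\n", object@auc))
})
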