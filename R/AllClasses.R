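## Formal classes for the fatigue-recognition pipeline. Each class mirrors
## one stage of the analysis: simulation, preprocessing, synergy analysis,
## windowed features, model-ready datasets and evaluation reports.

#' Simulation configuration for synthetic sEMG trials
#'
#' Describes a cyclic-exercise (squat-like) multi-channel sEMG trial with a
#' planted muscle-synergy structure and a monotone fatigue trajectory.
#' Fatigue is expressed through two phenomenological handles: an amplitude
#' gain that rises from \code{gainStart} to \code{gainEnd} and a carrier
#' median frequency that falls from \code{mfStart} to \code{mfEnd} as the
#' normalised fatigue level goes from 0 to 1.
#'
#' @slot nChannels number of recorded muscle channels.
#' @slot fs sampling rate in Hz.
#' @slot duration trial duration in seconds.
#' @slot nSynergies number of latent synergies driving the channels.
#' @slot cycleRate movement cadence in repetitions per minute.
#' @slot mixingWeights nonnegative \code{nChannels x nSynergies} matrix.
#' @slot dominantChannels channels planted as top contributors.
#' @slot tonicLevel baseline (tonic) activation level in [0, 1) shared by
#'   all synergy envelopes; the phasic burst rides on top of it.
#' @slot fatigueProfile monotone function mapping time (s) to fatigue in
#'   [0, 1], with \code{f(0) = 0} and \code{f(duration) = 1}.
#' @slot mfStart,mfEnd carrier median-frequency endpoints in Hz.
#' @slot gainStart,gainEnd amplitude-gain endpoints (unitless).
#' @slot noiseFloor additive white-noise amplitude relative to the unit
#'   carrier scale.
#' @slot labelFractions length-2 vector: fraction of the trial labelled
#'   relaxed (from the start) and fatigued (from the end).
#' @slot seed integer seed making the trial reproducible.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nChannels = "integer", fs = "numeric", duration = "numeric",
    nSynergies = "integer", cycleRate = "numeric",
    mixingWeights = "matrix", dominantChannels = "integer",
    tonicLevel = "numeric", fatigueProfile = "function",
    mfStart = "numeric", mfEnd = "numeric",
    gainStart = "numeric", gainEnd = "numeric",
    noiseFloor = "numeric", labelFractions = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@cycleRate <= 0) msg <- c(msg, "cycleRate must be positive")
  if (any(object@mixingWeights < 0))
    msg <- c(msg, "mixingWeights must be entrywise nonnegative")
  if (!all(dim(object@mixingWeights) ==
           c(object@nChannels, object@nSynergies)))
    msg <- c(msg, "mixingWeights must be nChannels x nSynergies")
  if (object@mfEnd > object@mfStart)
    msg <- c(msg, "mfEnd must be <= mfStart (spectral left-shift)")
  if (object@mfStart >= object@fs / 2 || object@mfEnd <= 0)
    msg <- c(msg, "carrier frequencies must lie in (0, fs/2)")
  if (object@gainStart > object@gainEnd)
    msg <- c(msg, "gainStart must be <= gainEnd (amplitude rise)")
  if (object@tonicLevel < 0 || object@tonicLevel >= 1)
    msg <- c(msg, "tonicLevel must be in [0, 1)")
  if (length(object@labelFractions) != 2L ||
      any(object@labelFractions <= 0) || sum(object@labelFractions) > 1)
    msg <- c(msg, "labelFractions must be two positive fractions summing to <= 1")
  u <- object@fatigueProfile(seq(0, object@duration, length.out = 101))
  if (abs(u[1]) > 1e-8 || abs(u[101] - 1) > 1e-8 || any(diff(u) < -1e-10))
    msg <- c(msg, "fatigueProfile must be nondecreasing with f(0)=0, f(duration)=1")
  if (length(msg)) msg else TRUE
})

#' Default synergy mixing weights
#'
#' Builds the default nonnegative mixing matrix. Dominant channels carry
#' unit weight on their own synergy plus strong (0.7) weight on the other
#' synergies: prime movers co-contract across the whole cycle, which
#' keeps their envelope modulation shallow and their summed loading high.
#' Each remaining channel loads a single synergy at 0.9: accessory
#' muscles fire phase-locked to one movement phase, giving the envelope
#' matrix the channel-diverse burst structure that makes the planted rank
#' identifiable, while their summed (single-synergy) loading stays well
#' below the dominant channels'.
#'
#' @param nChannels number of channels.
#' @param nSynergies number of synergies.
#' @param dominantChannels indices of channels planted as dominant
#'   (one per synergy, recycled if fewer synergies).
#' @return a nonnegative \code{nChannels x nSynergies} matrix.
#' @export
defaultMixingWeights <- function(nChannels = 8L, nSynergies = 3L,
                                 dominantChannels = seq_len(nSynergies)) {
  W <- matrix(0, nChannels, nSynergies)
  for (i in seq_along(dominantChannels)) {
    ch <- dominantChannels[i]
    s <- ((i - 1L) %% nSynergies) + 1L
    W[ch, ] <- 0.7
    W[ch, s] <- 1.0
  }
  others <- setdiff(seq_len(nChannels), dominantChannels)
  for (j in seq_along(others))
    W[others[j], ((j - 1L) %% nSynergies) + 1L] <- 0.9
  W
}

#' Construct a simulation configuration
#'
#' @param nChannels,fs,duration,nSynergies,cycleRate,tonicLevel,seed see
#'   \linkS4class{SimConfig}.
#' @param mixingWeights nonnegative mixing matrix; defaults to
#'   \code{\link{defaultMixingWeights}}.
#' @param dominantChannels planted dominant channel indices.
#' @param fatigueProfile monotone time -> [0,1] map; default linear.
#' @param mfStart,mfEnd,gainStart,gainEnd,noiseFloor,labelFractions see
#'   \linkS4class{SimConfig}.
#' @return a \linkS4class{SimConfig} object.
#' @examples
#' cfg <- simConfig(duration = 10)
#' cfg
#' @export
simConfig <- function(nChannels = 8L, fs = 2000, duration = 40,
                      nSynergies = 3L, cycleRate = 40,
                      mixingWeights = NULL,
                      dominantChannels = seq_len(min(3L, nChannels)),
                      tonicLevel = 0.05,
                      fatigueProfile = NULL,
                      mfStart = 90, mfEnd = 60,
                      gainStart = 1.0, gainEnd = 1.5,
                      noiseFloor = 0.05,
                      labelFractions = c(0.3, 0.3),
                      seed = 1L) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (cycleRate <= 0) stop("cycleRate must be positive", call. = FALSE)
  nChannels <- as.integer(nChannels)
  nSynergies <- as.integer(nSynergies)
  if (is.null(mixingWeights))
    mixingWeights <- defaultMixingWeights(nChannels, nSynergies,
                                          as.integer(dominantChannels))
  if (!all(dim(mixingWeights) == c(nChannels, nSynergies)))
    stop(sprintf("mixingWeights must be %d x %d (channels x synergies)",
                 nChannels, nSynergies), call. = FALSE)
  if (is.null(fatigueProfile)) {
    dur <- duration
    fatigueProfile <- function(t) pmin(1, pmax(0, t / dur))
  }
  new("SimConfig", nChannels = nChannels, fs = fs, duration = duration,
      nSynergies = nSynergies, cycleRate = cycleRate,
      mixingWeights = mixingWeights,
      dominantChannels = as.integer(dominantChannels),
      tonicLevel = tonicLevel, fatigueProfile = fatigueProfile,
      mfStart = mfStart, mfEnd = mfEnd,
      gainStart = gainStart, gainEnd = gainEnd,
      noiseFloor = noiseFloor, labelFractions = labelFractions,
      seed = as.integer(seed))
}

#' Multi-channel sEMG recording
#'
#' A plain container for a sampled multi-channel signal: an
#' \code{n_samples x n_channels} numeric matrix plus its sampling rate.
#'
#' @slot data numeric matrix, samples in rows, channels in columns.
#' @slot fs sampling rate in Hz.
#' @slot channelNames channel labels (column names of \code{data}).
#' @exportClass RawRecording
setClass("RawRecording",
  representation(data = "matrix", fs = "numeric", channelNames = "character"))

setValidity("RawRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (any(!is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(object@channelNames) != ncol(object@data))
    msg <- c(msg, "one channel name per column required")
  if (length(msg)) msg else TRUE
})

#' Construct a RawRecording
#' @param data samples x channels numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channelNames optional channel labels; default \code{ch1..chN}.
#' @return a \linkS4class{RawRecording}.
#' @export
rawRecording <- function(data, fs, channelNames = NULL) {
  data <- as.matrix(data)
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(ncol(data)))
  colnames(data) <- channelNames
  new("RawRecording", data = data, fs = fs,
      channelNames = as.character(channelNames))
}

#' Ground truth of a simulated trial
#'
#' @slot fatigueLevel per-sample fatigue level in [0, 1], nondecreasing.
#' @slot trueH nonnegative \code{nSynergies x n_env_samples} matrix of
#'   latent synergy activations (at the envelope rate \code{envFs}).
#' @slot trueW nonnegative \code{nChannels x nSynergies} mixing matrix.
#' @slot envFs sampling rate of \code{trueH} rows, Hz.
#' @slot labelBoundaries list with elements \code{relaxed} and
#'   \code{fatigued}, each a \code{c(start, end)} time span in seconds.
#' @exportClass SimGroundTruth
setClass("SimGroundTruth",
  representation(fatigueLevel = "numeric", trueH = "matrix",
                 trueW = "matrix", envFs = "numeric",
                 labelBoundaries = "list"))

setValidity("SimGroundTruth", function(object) {
  msg <- character()
  if (any(object@trueH < 0) || any(object@trueW < 0))
    msg <- c(msg, "trueH and trueW must be nonnegative")
  if (any(diff(object@fatigueLevel) < -1e-12))
    msg <- c(msg, "fatigueLevel must be nondecreasing")
  if (length(msg)) msg else TRUE
})

#' A simulated trial: recording plus ground truth
#' @slot recording the generated \linkS4class{RawRecording}.
#' @slot groundTruth the matching \linkS4class{SimGroundTruth}.
#' @slot config the \linkS4class{SimConfig} used.
#' @exportClass SimulatedTrial
setClass("SimulatedTrial",
  representation(recording = "RawRecording",
                 groundTruth = "SimGroundTruth",
                 config = "SimConfig"))

#' Filtering configuration
#'
#' Zero-phase Butterworth band-pass (default 20--150 Hz, order 4), a
#' power-line notch (default 50 Hz, Q = 30) and the low-pass cutoff used
#' for envelope extraction before synergy analysis.
#'
#' @slot bandLow,bandHigh band-pass corner frequencies in Hz.
#' @slot bandOrder Butterworth order of the band-pass prototype.
#' @slot notchFreq,notchQ notch centre frequency (Hz) and quality factor.
#' @slot envelopeCutoff low-pass cutoff (Hz) for the rectified envelope.
#' @slot edgeTrim seconds flagged as filter transient at each end,
#'   excluded from windowing by downstream steps.
#' @exportClass FilterConfig
setClass("FilterConfig",
  representation(bandLow = "numeric", bandHigh = "numeric",
                 bandOrder = "integer", notchFreq = "numeric",
                 notchQ = "numeric", envelopeCutoff = "numeric",
                 edgeTrim = "numeric"))

#' Construct a FilterConfig
#' @param bandLow,bandHigh,bandOrder,notchFreq,notchQ,envelopeCutoff,edgeTrim
#'   see \linkS4class{FilterConfig}.
#' @return a \linkS4class{FilterConfig}.
#' @export
filterConfig <- function(bandLow = 20, bandHigh = 150, bandOrder = 4L,
                         notchFreq = 50, notchQ = 30,
                         envelopeCutoff = 5, edgeTrim = 0.25) {
  if (bandLow <= 0 || bandHigh <= bandLow)
    stop("require 0 < bandLow < bandHigh", call. = FALSE)
  new("FilterConfig", bandLow = bandLow, bandHigh = bandHigh,
      bandOrder = as.integer(bandOrder), notchFreq = notchFreq,
      notchQ = notchQ, envelopeCutoff = envelopeCutoff,
      edgeTrim = edgeTrim)
}

#' Result of muscle-synergy analysis
#'
#' Holds the factorisation of the envelope matrix \code{V} (samples x
#' channels) as \code{V = W H + E} with nonnegative \code{W} (samples x k,
#' basis activations) and \code{H} (k x channels, channel loadings), the
#' VAF-versus-k curve, the selected synergy count and the ranked channel
#' contribution scores.
#'
#' @slot W,H,E factor and residual matrices.
#' @slot vafByK data.frame with columns \code{k, mean, max, min}.
#' @slot kSelected smallest k whose mean VAF exceeds the threshold.
#' @slot contributions per-channel summed normalised loading.
#' @slot channelsSelected top-ranked channel indices.
#' @exportClass SynergyResult
setClass("SynergyResult",
  representation(W = "matrix", H = "matrix", E = "matrix",
                 vafByK = "data.frame", kSelected = "integer",
                 contributions = "numeric", channelsSelected = "integer"))

#' Sliding-window configuration
#' @slot windowMs window length in milliseconds.
#' @slot stepMs step (hop) in milliseconds.
#' @slot fs sampling rate in Hz.
#' @exportClass WindowConfig
setClass("WindowConfig",
  representation(windowMs = "numeric", stepMs = "numeric", fs = "numeric"))

setValidity("WindowConfig", function(object) {
  w <- round(object@windowMs * object@fs / 1000)
  s <- round(object@stepMs * object@fs / 1000)
  msg <- character()
  if (w < 4) msg <- c(msg, "window must span at least 4 samples")
  if (s > w) msg <- c(msg, "step must not exceed window length")
  if (s < 1) msg <- c(msg, "step must span at least 1 sample")
  if (length(msg)) msg else TRUE
})

#' Construct a WindowConfig
#' @param windowMs,stepMs,fs see \linkS4class{WindowConfig}.
#' @return a \linkS4class{WindowConfig}.
#' @export
windowConfig <- function(windowMs = 100, stepMs = 25, fs = 2000) {
  new("WindowConfig", windowMs = windowMs, stepMs = stepMs, fs = fs)
}

#' Windowed feature matrix for one channel
#'
#' @slot values \code{n_windows x n_features} matrix; the canonical full
#'   set, in fixed column order, is RMS, IEMG, WL, SSC, MF, RMSF, SE, FD.
#' @slot windowTimes window-centre times in seconds.
#' @slot channel source channel index.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", windowTimes = "numeric",
                 channel = "integer"))

#' Model-ready labelled dataset
#'
#' @slot sequences list of \code{T x F} numeric matrices (normalised,
#'   equal length).
#' @slot labels integer vector, 0 = relaxed, 1 = fatigued.
#' @slot groups trial identifier per sequence (for group-aware splits).
#' @slot featureNames names of the F feature columns.
#' @exportClass LabeledDataset
setClass("LabeledDataset",
  representation(sequences = "list", labels = "integer",
                 groups = "character", featureNames = "character"))

setValidity("LabeledDataset", function(object) {
  msg <- character()
  if (length(object@sequences) != length(object@labels))
    msg <- c(msg, "one label per sequence required")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 (relaxed) or 1 (fatigued)")
  if (length(object@sequences)) {
    d <- vapply(object@sequences, dim, integer(2))
    if (length(unique(d[1, ])) != 1L || length(unique(d[2, ])) != 1L)
      msg <- c(msg, "all sequences must share the same dimensions")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledDataset
#' @param sequences list of \code{T x F} matrices.
#' @param labels binary labels (0/1), one per sequence.
#' @param groups trial/participant identifiers, one per sequence.
#' @param featureNames feature column names.
#' @return a \linkS4class{LabeledDataset}.
#' @export
labeledDataset <- function(sequences, labels, groups = NULL,
                           featureNames = NULL) {
  if (is.null(groups)) groups <- rep("trial1", length(sequences))
  if (is.null(featureNames)) {
    featureNames <- if (length(sequences)) {
      cn <- colnames(sequences[[1]])
      if (is.null(cn)) paste0("f", seq_len(ncol(sequences[[1]]))) else cn
    } else character()
  }
  new("LabeledDataset", sequences = sequences, labels = as.integer(labels),
      groups = as.character(groups), featureNames = featureNames)
}

#' Classifier configuration
#'
#' Architecture and optimisation settings shared by the Transformer
#' encoder and the baselines. \code{dModel} must be divisible by
#' \code{nHeads}.
#'
#' @slot dModel embedding width.
#' @slot nHeads attention heads.
#' @slot nLayers encoder layers (also LSTM hidden-layer count analogue).
#' @slot ffDim position-wise feed-forward width.
#' @slot dropout dropout fraction in [0, 1).
#' @slot lr Adam learning rate.
#' @slot epochs training epochs.
#' @slot batchSize minibatch size.
#' @slot seed RNG seed for init, shuffling and dropout.
#' @slot featureSubset integer indices of input features used
#'   (\code{integer(0)} = all).
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(dModel = "integer", nHeads = "integer", nLayers = "integer",
                 ffDim = "integer", dropout = "numeric", lr = "numeric",
                 epochs = "integer", batchSize = "integer", seed = "integer",
                 featureSubset = "integer"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@dModel %% object@nHeads != 0L)
    msg <- c(msg, "dModel must be divisible by nHeads")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelConfig
#' @param dModel,nHeads,nLayers,ffDim,dropout,lr,epochs,batchSize,seed,featureSubset
#'   see \linkS4class{ModelConfig}.
#' @return a \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(dModel = 64L, nHeads = 4L, nLayers = 2L,
                        ffDim = 128L, dropout = 0.1, lr = 1e-3,
                        epochs = 50L, batchSize = 32L, seed = 1L,
                        featureSubset = integer(0)) {
  new("ModelConfig", dModel = as.integer(dModel), nHeads = as.integer(nHeads),
      nLayers = as.integer(nLayers), ffDim = as.integer(ffDim),
      dropout = dropout, lr = lr, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), seed = as.integer(seed),
      featureSubset = as.integer(featureSubset))
}

#' Evaluation report
#'
#' @slot counts named vector \code{c(tp, tn, fp, fn)}.
#' @slot metrics data.frame with columns \code{metric, mean, sd} (sd is NA
#'   when no fold-wise replication is available).
#' @slot rocPoints data.frame with columns \code{fpr, tpr}.
#' @slot auc area under the ROC curve.
#' @slot attribution named per-feature importance scores (mean |Shapley|).
#' @slot comparisonTests list of model-comparison test results.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(counts = "numeric", metrics = "data.frame",
                 rocPoints = "data.frame", auc = "numeric",
                 attribution = "numeric", comparisonTests = "list"))
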