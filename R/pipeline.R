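## End-to-end orchestration: simulate -> filter -> synergy -> features ->
## dataset -> train -> evaluate, fully determined by one master seed.

#' Envelope matrix of a trial, ready for synergy analysis
#'
#' Band-pass + notch filtering, edge trimming, rectified 5 Hz envelope
#' and decimation to ~50 Hz.
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param fcfg a \linkS4class{FilterConfig}.
#' @param targetFs decimated envelope rate in Hz.
#' @return nonnegative matrix (decimated samples x channels).
#' @export
envelopeMatrix <- function(rec, fcfg = filterConfig(), targetFs = 50) {
  filt <- preprocessRecording(rec, fcfg)
  filt <- trimEdges(filt, fcfg@edgeTrim)
  env <- rectifyEnvelope(filt, fcfg)
  decimateEnvelope(env, samplingRate(rec), targetFs)$env
}

#' Aggregate channel contributions across trials by mean rank
#'
#' @param contribList list of per-trial contribution-score vectors.
#' @param topC channels to select.
#' @return list with \code{meanRank} per channel and
#'   \code{channelsSelected} (lowest mean rank; ties by channel index).
#' @export
aggregateContributions <- function(contribList, topC = 3L) {
  ranks <- vapply(contribList, function(s) rank(-s, ties.method = "first"),
                  numeric(length(contribList[[1]])))
  meanRank <- rowMeans(ranks)
  ord <- order(meanRank, seq_along(meanRank))
  list(meanRank = meanRank,
       channelsSelected = as.integer(ord[seq_len(topC)]))
}

#' Build a labelled sequence dataset from one channel of a trial
#'
#' Filters the channel, extracts windowed features, labels windows from
#' the trial ground truth, min-max normalises per trial and cuts
#' fixed-length sub-sequences.
#'
#' @param trial a \linkS4class{SimulatedTrial}.
#' @param channel channel index to use.
#' @param wcfg a \linkS4class{WindowConfig}.
#' @param fcfg a \linkS4class{FilterConfig}.
#' @param seqLen,stride sub-sequence length and hop, in windows.
#' @param group trial identifier.
#' @param filtered optional pre-filtered \linkS4class{RawRecording}
#'   (already trimmed), to avoid refiltering.
#' @return a \linkS4class{LabeledDataset}.
#' @export
trialDataset <- function(trial, channel, wcfg = NULL,
                         fcfg = filterConfig(), seqLen = 16L,
                         stride = seqLen %/% 2L, group = "trial1",
                         filtered = NULL) {
  rec <- recording(trial)
  if (is.null(wcfg)) wcfg <- windowConfig(fs = samplingRate(rec))
  if (is.null(filtered))
    filtered <- trimEdges(preprocessRecording(rec, fcfg), fcfg@edgeTrim)
  x <- signalData(filtered)[, channel]
  fm <- extractFeatures(x, wcfg, channel = channel)
  # window times are relative to the trimmed signal; shift to trial time
  times <- windowTimes(fm) + fcfg@edgeTrim
  lab <- assignLabels(times, groundTruth(trial))
  norm <- minMaxNormalize(featureValues(fm))$x
  buildSequences(norm, lab, len = seqLen, stride = stride, group = group)
}

#' Merge labelled datasets
#' @param ... \linkS4class{LabeledDataset} objects with matching features.
#' @return the pooled \linkS4class{LabeledDataset}.
#' @export
mergeDatasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && is.list(ds[[1]]) && !is(ds[[1]], "LabeledDataset"))
    ds <- ds[[1]]
  labeledDataset(
    do.call(c, lapply(ds, sequences)),
    do.call(c, lapply(ds, labels2)),
    do.call(c, lapply(ds, groups)),
    ds[[1]]@featureNames)
}

#' Cross-validated training and scoring
#'
#' Trains on each fold's complement within the training indices and
#' scores on the held-out fold.
#'
#' @param dataset a \linkS4class{LabeledDataset}.
#' @param splits a split plan from \code{\link{splitCV}}.
#' @param trainer function(dataset) returning a classifier with a
#'   \code{\link{predictProb}} method.
#' @return data.frame of per-fold acc/pre/recall/f1.
#' @export
crossValidate <- function(dataset, splits, trainer) {
  res <- lapply(seq_along(splits$folds), function(f) {
    valIdx <- splits$folds[[f]]
    trIdx <- setdiff(splits$trainIdx, valIdx)
    mod <- trainer(subsetDataset(dataset, trIdx))
    val <- subsetDataset(dataset, valIdx)
    pred <- predictProb(mod, val)
    m <- suppressWarnings(
      classificationMetrics(confusionCounts(labels2(val), pred$label)))
    data.frame(fold = f, acc = m$acc, pre = m$pre, recall = m$recall,
               f1 = m$f1)
  })
  do.call(rbind, res)
}

#' Run the full fatigue-recognition pipeline on simulated data
#'
#' Simulates trials, selects the synergy count and dominant channels,
#' extracts and fuses the eight features from the top channel, trains the
#' Transformer (and optionally the baselines) with a stratified 80/20
#' holdout plus 5-fold cross-validation, and evaluates on the holdout.
#'
#' @param seed master seed driving every random component.
#' @param nTrials simulated trials pooled into the dataset.
#' @param duration per-trial duration in seconds.
#' @param mcfg a \linkS4class{ModelConfig} for the classifiers.
#' @param includeBaselines also train the LSTM and boosted-tree models
#'   and run the Friedman/Nemenyi comparison over CV folds.
#' @param includeShapley compute permutation-sampling attribution for
#'   the Transformer on the holdout.
#' @param vafThreshold synergy-count selection threshold.
#' @param nRestarts NMF restarts.
#' @param seqLen,stride sub-sequence geometry, in windows.
#' @return a list report: synergy selection, per-model CV metrics,
#'   holdout metrics, ROC/AUC, optional attribution and comparison test,
#'   plus a timestamp.
#' @export
runPipeline <- function(seed = 1L, nTrials = 3L, duration = 40,
                        mcfg = modelConfig(dModel = 32L, nHeads = 4L,
                                           nLayers = 2L, ffDim = 64L,
                                           epochs = 30L, seed = seed),
                        includeBaselines = TRUE,
                        includeShapley = FALSE,
                        vafThreshold = 0.95, nRestarts = 10L,
                        seqLen = 16L, stride = 8L) {
  fcfg <- filterConfig()
  trials <- lapply(seq_len(nTrials), function(i)
    generateTrial(simConfig(duration = duration,
                            seed = deriveSeed(seed, i))))
  ## synergy stage: k from the first trial, contributions from all
  envs <- lapply(trials, function(tr)
    envelopeMatrix(recording(tr), fcfg))
  sel <- selectK(envs[[1]], threshold = vafThreshold,
                 nRestarts = nRestarts, seed = deriveSeed(seed, 50))
  contribs <- lapply(seq_along(envs), function(i) {
    fit <- nmfDecompose(envs[[i]], sel$kSelected, nRestarts = nRestarts,
                        seed = deriveSeed(seed, 60 + i))
    contributionScores(fit$H)$scores
  })
  agg <- aggregateContributions(contribs)
  topChannel <- agg$channelsSelected[1]
  ## dataset from the top channel of every trial
  dsets <- lapply(seq_along(trials), function(i)
    trialDataset(trials[[i]], topChannel, seqLen = seqLen,
                 stride = stride, group = paste0("trial", i)))
  dataset <- mergeDatasets(dsets)
  splits <- splitCV(dataset, seed = deriveSeed(seed, 70))
  trainers <- list(
    transformer = function(d) trainTransformer(d, mcfg))
  if (includeBaselines) {
    trainers$lstm <- function(d) trainLSTM(d, mcfg)
    trainers$xgboost <- function(d) trainXGBoost(d, mcfg)
  }
  cv <- lapply(trainers, function(tr) crossValidate(dataset, splits, tr))
  ## final fit on the full training set, evaluated on the holdout
  trainSet <- subsetDataset(dataset, splits$trainIdx)
  testSet <- subsetDataset(dataset, splits$testIdx)
  final <- trainTransformer(trainSet, mcfg)
  report <- evaluateClassifier(final, testSet, foldMetrics = cv$transformer)
  out <- list(
    seed = seed,
    nSequences = length(sequences(dataset)),
    kSelected = sel$kSelected,
    vafByK = sel$vafByK,
    contributionMeanRank = agg$meanRank,
    channelsSelected = agg$channelsSelected,
    cvMetrics = lapply(cv, function(d) d[, c("acc", "pre", "recall", "f1")]),
    holdout = list(counts = report@counts,
                   metrics = report@metrics,
                   auc = report@auc))
  if (includeBaselines) {
    accTable <- vapply(cv, function(d) d$acc, numeric(nrow(cv[[1]])))
    out$comparison <- friedmanNemenyi(accTable)
  }
  if (includeShapley)
    out$attribution <- shapleyAttribution(final, testSet, nSamples = 100L,
                                          seed = deriveSeed(seed, 80))
  out$timestamp <- format(Sys.time(), tz = "UTC")
  out
}
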