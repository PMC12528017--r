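## Gradient-boosted-tree baseline. Trees do not consume sequences
## directly: each sequence is flattened to per-feature mean and standard
## deviation summaries before boosting.

#' Trained gradient-boosted-tree fatigue classifier
#' @slot booster the fitted xgboost handle.
#' @slot config the \linkS4class{ModelConfig} used.
#' @slot featureNames names of the flattened summary features.
#' @exportClass XGBClassifier
setClass("XGBClassifier",
  representation(booster = "ANY", config = "ModelConfig",
                 featureNames = "character"))

## mean and SD per feature column, one row per sequence
flattenSequences <- function(seqs, featureNames) {
  X <- t(vapply(seqs, function(s)
    c(colMeans(s), apply(s, 2, sd)),
    numeric(2L * ncol(seqs[[1]]))))
  colnames(X) <- c(paste0(featureNames, "_mean"),
                   paste0(featureNames, "_sd"))
  X
}

#' Train the gradient-boosted-tree baseline classifier
#'
#' Boosted trees (binary logistic objective) on sequence-aggregated
#' features: the per-sequence mean and SD of every input feature.
#' Deterministic given the config seed (single-threaded).
#'
#' @inheritParams trainTransformer
#' @param nrounds boosting rounds.
#' @param maxDepth tree depth.
#' @param eta learning rate.
#' @return an \linkS4class{XGBClassifier}.
#' @export
trainXGBoost <- function(dataset, config = modelConfig(), nrounds = 100L,
                         maxDepth = 4L, eta = 0.1) {
  stopifnot(is(dataset, "LabeledDataset"))
  seqs <- subsetFeatures(sequences(dataset), config@featureSubset)
  fn <- dataset@featureNames
  if (length(config@featureSubset)) fn <- fn[config@featureSubset]
  X <- flattenSequences(seqs, fn)
  dtrain <- xgboost::xgb.DMatrix(X, label = labels2(dataset))
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = maxDepth,
                  eta = eta, nthread = 1L, seed = config@seed),
    data = dtrain, nrounds = nrounds)
  new("XGBClassifier", booster = booster, config = config,
      featureNames = colnames(X))
}

#' @rdname predictProb
#' @export
setMethod("predictProb", "XGBClassifier", function(object, newdata, ...) {
  seqs <- if (is(newdata, "LabeledDataset")) sequences(newdata) else newdata
  seqs <- subsetFeatures(seqs, object@config@featureSubset)
  if (!length(seqs))
    return(list(prob = matrix(numeric(0), 0, 2,
                              dimnames = list(NULL,
                                              c("relaxed", "fatigued"))),
                label = integer(0)))
  fn <- sub("_mean$|_sd$", "", object@featureNames)
  X <- flattenSequences(seqs, unique(fn))
  p1 <- stats::predict(object@booster, xgboost::xgb.DMatrix(X))
  P <- cbind(relaxed = 1 - p1, fatigued = p1)
  list(prob = P, label = as.integer(p1 > 0.5))
})
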