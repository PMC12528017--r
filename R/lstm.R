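## Recurrent (LSTM) baseline: a single long short-term memory layer with
## hidden width dModel, mean-pooled hidden states and a linear two-class
## head, trained with Adam on cross-entropy via backpropagation through
## time. Shares the training contract (seeding, batching, NaN guard) with
## the Transformer.

#' Trained LSTM fatigue classifier
#' @slot params list of LSTM and head weights.
#' @slot config the \linkS4class{ModelConfig} used.
#' @slot seqLen,nFeatures input dimensions.
#' @slot featureNames input feature names.
#' @slot history per-epoch mean training loss.
#' @exportClass LSTMClassifier
setClass("LSTMClassifier",
  representation(params = "list", config = "ModelConfig",
                 seqLen = "integer", nFeatures = "integer",
                 featureNames = "character", history = "numeric"))

initLSTMParams <- function(nFeat, cfg) {
  Hd <- cfg@dModel
  b <- numeric(4L * Hd)
  b[(Hd + 1L):(2L * Hd)] <- 1  # forget-gate bias
  list(Wx = xavier(nFeat, 4L * Hd), Wh = xavier(Hd, 4L * Hd), b = b,
       Wc = xavier(Hd, 2L), bc = numeric(2L))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstmForward <- function(params, seqs, cfg) {
  B <- length(seqs); T <- nrow(seqs[[1]]); Hd <- cfg@dModel
  Xt <- lapply(seq_len(T), function(t)
    do.call(rbind, lapply(seqs, function(s) s[t, ])))
  H <- matrix(0, B, Hd); C <- matrix(0, B, Hd)
  steps <- vector("list", T)
  Hsum <- matrix(0, B, Hd)
  i1 <- seq_len(Hd); i2 <- Hd + i1; i3 <- 2L * Hd + i1; i4 <- 3L * Hd + i1
  for (t in seq_len(T)) {
    G <- Xt[[t]] %*% params$Wx + H %*% params$Wh +
      rep(params$b, each = B)
    ig <- sigmoid(G[, i1, drop = FALSE])
    fg <- sigmoid(G[, i2, drop = FALSE])
    gg <- tanh(G[, i3, drop = FALSE])
    og <- sigmoid(G[, i4, drop = FALSE])
    Cprev <- C
    C <- fg * Cprev + ig * gg
    tc <- tanh(C)
    Hprev <- H
    H <- og * tc
    steps[[t]] <- list(X = Xt[[t]], Hprev = Hprev, Cprev = Cprev,
                       i = ig, f = fg, g = gg, o = og, tc = tc)
    Hsum <- Hsum + H
  }
  P <- Hsum / T
  logits <- P %*% params$Wc + rep(params$bc, each = B)
  list(logits = logits, P = P, steps = steps)
}

lstmBackward <- function(params, fwd, dLogits, cfg) {
  Hd <- cfg@dModel
  T <- length(fwd$steps)
  B <- nrow(dLogits)
  grads <- treeZero(params)
  grads$Wc <- crossprod(fwd$P, dLogits)
  grads$bc <- colSums(dLogits)
  dPool <- dLogits %*% t(params$Wc) / T
  dH <- matrix(0, B, Hd); dC <- matrix(0, B, Hd)
  for (t in rev(seq_len(T))) {
    s <- fwd$steps[[t]]
    dh <- dH + dPool
    do_ <- dh * s$tc
    dC <- dC + dh * s$o * (1 - s$tc^2)
    di <- dC * s$g
    dg <- dC * s$i
    df <- dC * s$Cprev
    dCnext <- dC * s$f
    dG <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do_ * s$o * (1 - s$o))
    grads$Wx <- grads$Wx + crossprod(s$X, dG)
    grads$Wh <- grads$Wh + crossprod(s$Hprev, dG)
    grads$b <- grads$b + colSums(dG)
    dH <- dG %*% t(params$Wh)
    dC <- dCnext
  }
  grads
}

#' Train the recurrent (LSTM) baseline classifier
#'
#' @inheritParams trainTransformer
#' @return an \linkS4class{LSTMClassifier}.
#' @export
trainLSTM <- function(dataset, config = modelConfig()) {
  stopifnot(is(dataset, "LabeledDataset"))
  seqs <- subsetFeatures(sequences(dataset), config@featureSubset)
  y <- labels2(dataset)
  n <- length(seqs)
  if (n == 0) stop("empty dataset", call. = FALSE)
  T <- nrow(seqs[[1]]); nFeat <- ncol(seqs[[1]])
  history <- numeric(config@epochs)
  withSeed(config@seed, {
    params <- initLSTMParams(nFeat, config)
    opt <- adamInit(params)
    for (ep in seq_len(config@epochs)) {
      batches <- epochBatches(n, config@batchSize)
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        fwd <- lstmForward(params, seqs[idx], config)
        ce <- softmaxCE(fwd$logits, y[idx])
        if (!is.finite(ce$loss))
          stop(sprintf("NaN/Inf loss at epoch %d batch %d", ep, bi),
               call. = FALSE)
        grads <- lstmBackward(params, fwd, ce$dLogits, config)
        upd <- adamStep(params, grads, opt, config@lr)
        params <- upd$params; opt <- upd$state
        losses[bi] <- ce$loss
      }
      history[ep] <- mean(losses)
    }
  })
  fn <- dataset@featureNames
  if (length(config@featureSubset)) fn <- fn[config@featureSubset]
  new("LSTMClassifier", params = params, config = config,
      seqLen = as.integer(T), nFeatures = as.integer(nFeat),
      featureNames = fn, history = history)
}

#' @rdname predictProb
#' @export
setMethod("predictProb", "LSTMClassifier", function(object, newdata, ...) {
  seqs <- if (is(newdata, "LabeledDataset")) sequences(newdata) else newdata
  seqs <- subsetFeatures(seqs, object@config@featureSubset)
  if (!length(seqs))
    return(list(prob = matrix(numeric(0), 0, 2,
                              dimnames = list(NULL,
                                              c("relaxed", "fatigued"))),
                label = integer(0)))
  fwd <- lstmForward(object@params, seqs, object@config)
  P <- rowSoftmax(fwd$logits)
  colnames(P) <- c("relaxed", "fatigued")
  list(prob = P, label = as.integer(P[, 2] > 0.5))
})
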