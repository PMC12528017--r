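## Transformer-encoder fatigue classifier. Pipeline: linear input
## embedding + sinusoidal positional encoding -> nLayers encoder blocks
## (multi-head self-attention, position-wise feed-forward, residual
## connections, post-sublayer layer normalisation) -> mean pooling over
## time -> linear two-class head. Trained with Adam on cross-entropy;
## forward and backward passes are written out analytically.

#' Trained Transformer fatigue classifier
#' @slot params nested list of weight matrices.
#' @slot config the \linkS4class{ModelConfig} used.
#' @slot seqLen,nFeatures input sequence dimensions.
#' @slot featureNames names of the (possibly subset) input features.
#' @slot history per-epoch mean training loss.
#' @exportClass TransformerClassifier
setClass("TransformerClassifier",
  representation(params = "list", config = "ModelConfig",
                 seqLen = "integer", nFeatures = "integer",
                 featureNames = "character", history = "numeric"))

initTransformerParams <- function(nFeat, cfg) {
  d <- cfg@dModel; ff <- cfg@ffDim
  layers <- vector("list", cfg@nLayers)
  for (l in seq_len(cfg@nLayers)) {
    layers[[l]] <- list(
      Wq = xavier(d, d), Wk = xavier(d, d), Wv = xavier(d, d),
      Wo = xavier(d, d), bo = numeric(d),
      g1 = rep(1, d), b1 = numeric(d),
      W1 = xavier(d, ff), b1f = numeric(ff),
      W2 = xavier(ff, d), b2f = numeric(d),
      g2 = rep(1, d), b2 = numeric(d))
  }
  list(We = xavier(nFeat, d), be = numeric(d), layers = layers,
       Wc = xavier(d, 2L), bc = numeric(2L))
}

dropoutMask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix(rbinom(nr * nc, 1L, 1 - p), nr, nc) / (1 - p)
}

## Forward pass over a stacked batch. Returns logits plus caches needed
## for the backward pass; attention weights kept when keepAttn.
transformerForward <- function(params, Xb, B, T, cfg, train = FALSE,
                               keepAttn = FALSE) {
  d <- cfg@dModel; nh <- cfg@nHeads; dk <- d %/% nh
  PE <- positionalEncoding(T, d)
  H <- Xb %*% params$We + rep(params$be, each = nrow(Xb)) +
    PE[rep(seq_len(T), times = B), ]
  caches <- vector("list", length(params$layers))
  attnAll <- if (keepAttn) vector("list", length(params$layers)) else NULL
  for (l in seq_along(params$layers)) {
    p <- params$layers[[l]]
    Hin <- H
    Q <- Hin %*% p$Wq; K <- Hin %*% p$Wk; V <- Hin %*% p$Wv
    O <- matrix(0, nrow(Hin), d)
    A <- vector("list", B)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * T + 1L):(b * T)
      Ab <- vector("list", nh)
      for (h in seq_len(nh)) {
        ch <- ((h - 1L) * dk + 1L):(h * dk)
        att <- scaledDotAttention(Q[rb, ch, drop = FALSE],
                                  K[rb, ch, drop = FALSE],
                                  V[rb, ch, drop = FALSE])
        O[rb, ch] <- att$output
        Ab[[h]] <- att$weights
      }
      A[[b]] <- Ab
    }
    M <- O %*% p$Wo + rep(p$bo, each = nrow(O))
    dm1 <- if (train) dropoutMask(nrow(M), d, cfg@dropout) else NULL
    if (!is.null(dm1)) M <- M * dm1
    ln1 <- layerNormForward(Hin + M, p$g1, p$b1)
    N1 <- ln1$Y
    Z1 <- N1 %*% p$W1 + rep(p$b1f, each = nrow(N1))
    Ar <- pmax(Z1, 0)
    Fo <- Ar %*% p$W2 + rep(p$b2f, each = nrow(Ar))
    dm2 <- if (train) dropoutMask(nrow(Fo), d, cfg@dropout) else NULL
    if (!is.null(dm2)) Fo <- Fo * dm2
    ln2 <- layerNormForward(N1 + Fo, p$g2, p$b2)
    H <- ln2$Y
    caches[[l]] <- list(Hin = Hin, Q = Q, K = K, V = V, A = A, O = O,
                        dm1 = dm1, ln1 = ln1, N1 = N1, Z1 = Z1, Ar = Ar,
                        dm2 = dm2, ln2 = ln2)
    if (keepAttn) attnAll[[l]] <- A
  }
  grp <- rep(seq_len(B), each = T)
  P <- rowsum(H, grp) / T
  rownames(P) <- NULL
  logits <- P %*% params$Wc + rep(params$bc, each = B)
  list(logits = logits, P = P, H = H, caches = caches, attn = attnAll)
}

transformerBackward <- function(params, fwd, dLogits, Xb, B, T, cfg) {
  d <- cfg@dModel; nh <- cfg@nHeads; dk <- d %/% nh
  grads <- treeZero(params)
  grads$Wc <- crossprod(fwd$P, dLogits)
  grads$bc <- colSums(dLogits)
  dP <- dLogits %*% t(params$Wc)
  dH <- dP[rep(seq_len(B), each = T), , drop = FALSE] / T
  for (l in rev(seq_along(params$layers))) {
    p <- params$layers[[l]]
    cc <- fwd$caches[[l]]
    g <- grads$layers[[l]]
    lb2 <- layerNormBackward(dH, cc$ln2, p$g2)
    g$g2 <- lb2$dg; g$b2 <- lb2$db
    dR2 <- lb2$dX
    dFo <- dR2
    if (!is.null(cc$dm2)) dFo <- dFo * cc$dm2
    g$W2 <- crossprod(cc$Ar, dFo)
    g$b2f <- colSums(dFo)
    dAr <- dFo %*% t(p$W2)
    dZ1 <- dAr * (cc$Z1 > 0)
    g$W1 <- crossprod(cc$N1, dZ1)
    g$b1f <- colSums(dZ1)
    dN1 <- dR2 + dZ1 %*% t(p$W1)
    lb1 <- layerNormBackward(dN1, cc$ln1, p$g1)
    g$g1 <- lb1$dg; g$b1 <- lb1$db
    dR1 <- lb1$dX
    dM <- dR1
    if (!is.null(cc$dm1)) dM <- dM * cc$dm1
    g$Wo <- crossprod(cc$O, dM)
    g$bo <- colSums(dM)
    dO <- dM %*% t(p$Wo)
    dQ <- matrix(0, nrow(dO), d)
    dK <- matrix(0, nrow(dO), d)
    dV <- matrix(0, nrow(dO), d)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * T + 1L):(b * T)
      for (h in seq_len(nh)) {
        ch <- ((h - 1L) * dk + 1L):(h * dk)
        A <- cc$A[[b]][[h]]
        dOb <- dO[rb, ch, drop = FALSE]
        Vb <- cc$V[rb, ch, drop = FALSE]
        dA <- tcrossprod(dOb, Vb)
        dV[rb, ch] <- crossprod(A, dOb)
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(dk)
        dQ[rb, ch] <- dS %*% cc$K[rb, ch, drop = FALSE]
        dK[rb, ch] <- crossprod(dS, cc$Q[rb, ch, drop = FALSE])
      }
    }
    g$Wq <- crossprod(cc$Hin, dQ)
    g$Wk <- crossprod(cc$Hin, dK)
    g$Wv <- crossprod(cc$Hin, dV)
    dH <- dR1 + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    grads$layers[[l]] <- g
  }
  grads$We <- crossprod(Xb, dH)
  grads$be <- colSums(dH)
  grads
}

subsetFeatures <- function(seqs, subset) {
  if (!length(subset)) return(seqs)
  lapply(seqs, function(s) s[, subset, drop = FALSE])
}

#' Train the Transformer-encoder fatigue classifier
#'
#' @param dataset a \linkS4class{LabeledDataset} of equal-length,
#'   normalised sequences with binary labels.
#' @param config a \linkS4class{ModelConfig}; \code{featureSubset}
#'   restricts the input columns (single-feature runs reuse the identical
#'   architecture with input width 1).
#' @return a \linkS4class{TransformerClassifier}.
#' @examples
#' \donttest{
#' ds <- labeledDataset(
#'   lapply(1:20, function(i) matrix(rnorm(16 * 2, mean = (i > 10)), 16)),
#'   rep(0:1, each = 10))
#' mod <- trainTransformer(ds, modelConfig(dModel = 8, nHeads = 2,
#'                                         nLayers = 1, ffDim = 16,
#'                                         epochs = 5))
#' }
#' @export
trainTransformer <- function(dataset, config = modelConfig()) {
  stopifnot(is(dataset, "LabeledDataset"))
  validObject(config)
  seqs <- subsetFeatures(sequences(dataset), config@featureSubset)
  y <- labels2(dataset)
  n <- length(seqs)
  if (n == 0) stop("empty dataset", call. = FALSE)
  T <- nrow(seqs[[1]]); nFeat <- ncol(seqs[[1]])
  history <- numeric(config@epochs)
  withSeed(config@seed, {
    params <- initTransformerParams(nFeat, config)
    opt <- adamInit(params)
    for (ep in seq_len(config@epochs)) {
      batches <- epochBatches(n, config@batchSize)
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        Xb <- stackSequences(seqs[idx])
        fwd <- transformerForward(params, Xb, length(idx), T, config,
                                  train = TRUE)
        ce <- softmaxCE(fwd$logits, y[idx])
        if (!is.finite(ce$loss))
          stop(sprintf(
            "NaN/Inf loss at epoch %d batch %d; lr=%g may be too high",
            ep, bi, config@lr), call. = FALSE)
        grads <- transformerBackward(params, fwd, ce$dLogits, Xb,
                                     length(idx), T, config)
        upd <- adamStep(params, grads, opt, config@lr)
        params <- upd$params; opt <- upd$state
        losses[bi] <- ce$loss
      }
      history[ep] <- mean(losses)
    }
  })
  fn <- dataset@featureNames
  if (length(config@featureSubset)) fn <- fn[config@featureSubset]
  new("TransformerClassifier", params = params, config = config,
      seqLen = as.integer(T), nFeatures = as.integer(nFeat),
      featureNames = fn, history = history)
}

#' @rdname predictProb
#' @export
setMethod("predictProb", "TransformerClassifier",
          function(object, newdata, ...) {
  seqs <- if (is(newdata, "LabeledDataset")) sequences(newdata) else newdata
  seqs <- subsetFeatures(seqs, object@config@featureSubset)
  if (!length(seqs))
    return(list(prob = matrix(numeric(0), 0, 2,
                              dimnames = list(NULL,
                                              c("relaxed", "fatigued"))),
                label = integer(0)))
  B <- length(seqs)
  fwd <- transformerForward(object@params, stackSequences(seqs), B,
                            object@seqLen, object@config, train = FALSE)
  P <- rowSoftmax(fwd$logits)
  colnames(P) <- c("relaxed", "fatigued")
  list(prob = P, label = as.integer(P[, 2] > 0.5))
})

#' Attention weights of a trained Transformer on new sequences
#'
#' @param model a \linkS4class{TransformerClassifier}.
#' @param newdata a \linkS4class{LabeledDataset} or list of sequences.
#' @return nested list \code{[[layer]][[sequence]][[head]]} of
#'   row-stochastic attention matrices.
#' @export
attentionWeights <- function(model, newdata) {
  seqs <- if (is(newdata, "LabeledDataset")) sequences(newdata) else newdata
  seqs <- subsetFeatures(seqs, model@config@featureSubset)
  fwd <- transformerForward(model@params, stackSequences(seqs),
                            length(seqs), model@seqLen, model@config,
                            train = FALSE, keepAttn = TRUE)
  fwd$attn
}
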