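## Minimal neural-network toolkit used by the sequence classifiers:
## nested-list parameter trees, Adam, row softmax, layer normalisation
## with analytic backward passes. Everything is plain R matrix algebra;
## training is seeded and fully deterministic.

## Apply a function elementwise over parallel trees of arrays.
treeMap <- function(f, a, b = NULL, c = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a))
      out[[i]] <- treeMap(f, a[[i]],
                          if (!is.null(b)) b[[i]],
                          if (!is.null(c)) c[[i]])
    out
  } else {
    if (is.null(b)) f(a) else if (is.null(c)) f(a, b) else f(a, b, c)
  }
}

treeZero <- function(a) treeMap(function(x) x * 0, a)

adamInit <- function(params) {
  list(m = treeZero(params), v = treeZero(params), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- treeMap(function(m, g) beta1 * m + (1 - beta1) * g,
                     state$m, grads)
  state$v <- treeMap(function(v, g) beta2 * v + (1 - beta2) * g^2,
                     state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- treeMap(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

rowSoftmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

## Layer normalisation over each row, with affine gain/bias.
layerNormForward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  invstd <- 1 / sqrt(rowMeans(Xc^2) + eps)
  xhat <- Xc * invstd
  list(Y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, invstd = invstd)
}

layerNormBackward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$invstd * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

#' Scaled dot-product attention
#'
#' \code{softmax(Q K' / sqrt(d_k)) V}: each query row attends over the
#' key/value rows with weights that sum to one.
#'
#' @param Q query matrix (\code{T_q x d_k}).
#' @param K key matrix (\code{T_kv x d_k}).
#' @param V value matrix (\code{T_kv x d_v}).
#' @return list with \code{output} (\code{T_q x d_v}) and \code{weights}
#'   (row-stochastic \code{T_q x T_kv}).
#' @examples
#' scaledDotAttention(matrix(c(1, 0), 1), diag(2), matrix(c(10, 20)))
#' @export
scaledDotAttention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K))
    stop(sprintf("key dimension mismatch: Q has %d columns, K has %d",
                 ncol(Q), ncol(K)), call. = FALSE)
  if (nrow(K) != nrow(V))
    stop(sprintf("sequence-length mismatch: K has %d rows, V has %d",
                 nrow(K), nrow(V)), call. = FALSE)
  A <- rowSoftmax(tcrossprod(Q, K) / sqrt(ncol(Q)))
  list(output = A %*% V, weights = A)
}

#' Sinusoidal positional encoding
#'
#' Interleaved sine/cosine at geometrically spaced wavelengths (base
#' 10000): column 2i-1 holds \code{sin(pos / 10000^((i-1)/(d/2)))},
#' column 2i the matching cosine. Position 0 encodes as (0, 1, 0, 1, ...).
#'
#' @param T sequence length.
#' @param dModel embedding width (even).
#' @return \code{T x dModel} matrix with values in [-1, 1].
#' @export
positionalEncoding <- function(T, dModel) {
  if (dModel %% 2 != 0) stop("dModel must be even", call. = FALSE)
  pos <- 0:(T - 1)
  PE <- matrix(0, T, dModel)
  for (i in seq_len(dModel / 2)) {
    wl <- 10000^((i - 1) / (dModel / 2))
    PE[, 2 * i - 1] <- sin(pos / wl)
    PE[, 2 * i] <- cos(pos / wl)
  }
  PE
}

## Cross-entropy on softmax logits; y is 0/1. Returns loss and dLogits.
softmaxCE <- function(logits, y) {
  P <- rowSoftmax(logits)
  n <- nrow(P)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  Y <- matrix(0, n, ncol(P))
  Y[idx] <- 1
  list(loss = loss, dLogits = (P - Y) / n, prob = P)
}

## Stack a list of T x F sequence matrices into one (B*T) x F matrix.
stackSequences <- function(seqs) do.call(rbind, seqs)

## Seeded minibatch index schedule for one epoch.
epochBatches <- function(n, batchSize) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batchSize))
}
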