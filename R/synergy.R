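## Muscle-synergy analysis: V (samples x channels) ~ W H with W >= 0
## (samples x k, synergy activations) and H >= 0 (k x channels, channel
## loadings), fitted by multiplicative updates minimising the Frobenius
## reconstruction error, scored by VAF = 1 - ||V - WH||_F^2 / ||V||_F^2.

#' Variance accounted for by a factorisation
#'
#' @param V nonnegative data matrix.
#' @param W,H factor matrices with \code{V ~ W %*% H}.
#' @return VAF in [0, 1]: \code{1 - ||V - WH||^2_F / ||V||^2_F}.
#' @examples
#' V <- matrix(c(1, 0, 0, 1), 2)
#' vaf(V, diag(2), diag(2))
#' @export
vaf <- function(V, W, H) {
  tot <- sum(V^2)
  if (tot == 0) stop("VAF undefined for an all-zero matrix", call. = FALSE)
  max(0, 1 - sum((V - W %*% H)^2) / tot)
}

## One multiplicative-update fit from a random nonnegative start.
nmfFitOnce <- function(V, k, maxIter, tol, seed) {
  m <- nrow(V); n <- ncol(V)
  eps <- 1e-12
  withSeed(seed, {
    W <- matrix(runif(m * k, 0.1, 1), m, k) * sqrt(mean(V) / k)
    H <- matrix(runif(k * n, 0.1, 1), k, n) * sqrt(mean(V) / k)
  })
  errPrev <- Inf
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    if (it %% 10L == 0L || it == maxIter) {
      err <- sum((V - W %*% H)^2)
      if (is.finite(errPrev) && errPrev - err <= tol * max(errPrev, eps))
        break
      errPrev <- err
    }
  }
  list(W = W, H = H, err = sum((V - W %*% H)^2))
}

#' Non-negative matrix factorisation by multiplicative updates
#'
#' Fits \code{V ~ W H} under nonnegativity, keeping the best of
#' \code{nRestarts} random restarts by final Frobenius error. The scale
#' indeterminacy is resolved by normalising each column of \code{W} to
#' unit maximum with the compensating scale absorbed into \code{H}, which
#' leaves the reconstruction (and VAF) unchanged.
#'
#' @param V nonnegative matrix, samples x channels.
#' @param k factorisation rank (number of synergies), 1 <= k <= ncol(V).
#' @param nRestarts random restarts (default 20).
#' @param maxIter maximum update iterations per restart (default 500).
#' @param tol relative error-decrease tolerance for early stopping.
#' @param seed RNG seed; restart r uses a seed derived from it.
#' @return list with nonnegative \code{W}, \code{H}, residual \code{E} and
#'   the achieved \code{vaf}.
#' @export
nmfDecompose <- function(V, k, nRestarts = 20L, maxIter = 500L,
                         tol = 1e-6, seed = 1L) {
  V <- as.matrix(V)
  if (any(V < 0)) {
    bad <- which(apply(V, 2, function(col) any(col < 0)))
    stop(sprintf("negative entries in V (channel%s %s)",
                 if (length(bad) > 1) "s" else "",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (k < 1 || k > ncol(V))
    stop("k must lie in 1..ncol(V)", call. = FALSE)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- nmfFitOnce(V, k, maxIter, tol, deriveSeed(seed, r * 31 + k))
    if (is.null(best) || fit$err < best$err) best <- fit
  }
  cmax <- apply(best$W, 2, max)
  cmax[cmax == 0] <- 1
  W <- sweep(best$W, 2, cmax, "/")
  H <- sweep(best$H, 1, cmax, "*")
  list(W = W, H = H, E = V - W %*% H, vaf = vaf(V, W, H))
}

#' Select the synergy count by the VAF criterion
#'
#' Fits k = 1..ncol(V), repeating each fit \code{nReps} times from
#' different seeds to obtain mean/max/min VAF, and selects the smallest k
#' whose mean VAF exceeds \code{threshold}.
#'
#' @inheritParams nmfDecompose
#' @param threshold VAF threshold in (0, 1), default 0.95.
#' @param nReps repeated fits per k used for the VAF dispersion (each fit
#'   itself keeps the best of \code{nRestarts} starts).
#' @param maxK largest k examined (default \code{ncol(V)}).
#' @return list with \code{kSelected} and \code{vafByK} (data.frame with
#'   columns k, mean, max, min).
#' @export
selectK <- function(V, threshold = 0.95, nRestarts = 20L, nReps = 3L,
                    maxIter = 500L, tol = 1e-6, seed = 1L,
                    maxK = ncol(V)) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  ks <- seq_len(maxK)
  vafs <- matrix(NA_real_, length(ks), nReps)
  for (k in ks) for (rep in seq_len(nReps)) {
    fit <- nmfDecompose(V, k, nRestarts = max(1L, nRestarts %/% nReps),
                        maxIter = maxIter, tol = tol,
                        seed = deriveSeed(seed, k * 101 + rep))
    vafs[k, rep] <- fit$vaf
  }
  vafByK <- data.frame(k = ks,
                       mean = rowMeans(vafs),
                       max = apply(vafs, 1, max),
                       min = apply(vafs, 1, min))
  hit <- which(vafByK$mean > threshold)
  kSelected <- if (length(hit)) min(hit) else maxK
  list(kSelected = as.integer(kSelected), vafByK = vafByK)
}

#' Channel contribution scores from synergy loadings
#'
#' Each synergy's channel-loading vector (a row of \code{H}) is scaled to
#' unit maximum, and a channel's score is the sum of its normalised
#' loadings across synergies; scores are therefore invariant to rescaling
#' any single synergy. Degenerate all-zero synergies are dropped with a
#' warning. Ties rank by ascending channel index.
#'
#' @param H loading matrix, synergies in rows, channels in columns.
#' @param topC number of channels to select (default 3).
#' @return list with \code{scores} (per channel) and
#'   \code{channelsSelected} (indices of the top \code{topC} scores).
#' @export
contributionScores <- function(H, topC = 3L) {
  H <- as.matrix(H)
  rowMax <- apply(H, 1, max)
  keep <- rowMax > 0
  if (!all(keep)) {
    warning(sprintf("%d all-zero synergy(ies) excluded from scoring",
                    sum(!keep)))
    H <- H[keep, , drop = FALSE]
    rowMax <- rowMax[keep]
  }
  norm <- sweep(H, 1, rowMax, "/")
  scores <- colSums(norm)
  ord <- order(-scores, seq_along(scores))
  list(scores = scores,
       channelsSelected = as.integer(ord[seq_len(min(topC, length(scores)))]))
}

#' Full synergy analysis of an envelope matrix
#'
#' Runs \code{\link{selectK}}, refits at the selected k and ranks channel
#' contributions, returning everything as a \linkS4class{SynergyResult}.
#'
#' @inheritParams selectK
#' @param topC number of dominant channels to select.
#' @return a \linkS4class{SynergyResult}.
#' @export
synergyAnalysis <- function(V, threshold = 0.95, nRestarts = 20L,
                            nReps = 3L, maxIter = 500L, tol = 1e-6,
                            seed = 1L, topC = 3L, maxK = ncol(V)) {
  sel <- selectK(V, threshold, nRestarts, nReps, maxIter, tol, seed, maxK)
  fit <- nmfDecompose(V, sel$kSelected, nRestarts, maxIter, tol,
                      seed = deriveSeed(seed, 9999))
  contrib <- contributionScores(fit$H, topC)
  new("SynergyResult", W = fit$W, H = fit$H, E = fit$E,
      vafByK = sel$vafByK, kSelected = sel$kSelected,
      contributions = unname(contrib$scores),
      channelsSelected = contrib$channelsSelected)
}
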