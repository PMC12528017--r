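## Evaluation layer: confusion-based metrics (positive class = fatigued),
## ROC/AUC by threshold sweep, model-agnostic Shapley attribution by
## permutation sampling, and Friedman/Nemenyi model comparison.

#' Confusion counts
#'
#' @param labels true 0/1 labels (1 = fatigued, the positive class).
#' @param predictions predicted 0/1 labels.
#' @return named vector \code{c(tp, tn, fp, fn)}.
#' @export
confusionCounts <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions))
  c(tp = sum(labels == 1 & predictions == 1),
    tn = sum(labels == 0 & predictions == 0),
    fp = sum(labels == 0 & predictions == 1),
    fn = sum(labels == 1 & predictions == 0))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Undefined ratios (zero denominators) are reported as 0 with a warning
#' and listed in the \code{undefined} element.
#'
#' @param tp,tn,fp,fn confusion counts (or a named vector as first
#'   argument).
#' @return list with \code{acc}, \code{pre}, \code{recall}, \code{f1} and
#'   \code{undefined} (names of flagged metrics).
#' @examples
#' classificationMetrics(50, 40, 10, 0)
#' @export
classificationMetrics <- function(tp, tn, fp, fn) {
  if (length(tp) == 4L && is.null(dim(tp))) {
    cc <- tp; tp <- cc[["tp"]]; tn <- cc[["tn"]]
    fp <- cc[["fp"]]; fn <- cc[["fn"]]
  }
  undefined <- character()
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  acc <- ratio(tp + tn, tp + tn + fp + fn, "acc")
  pre <- ratio(tp, tp + fp, "pre")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- ratio(2 * pre * recall, pre + recall, "f1")
  if (length(undefined))
    warning(sprintf("undefined metric(s) reported as 0: %s",
                    paste(undefined, collapse = ", ")))
  list(acc = acc, pre = pre, recall = recall, f1 = f1,
       undefined = undefined)
}

#' ROC curve and AUC by threshold sweep
#'
#' Thresholds sweep the unique scores (equal scores grouped); the curve
#' runs from (0, 0) to (1, 1) and the AUC is the trapezoid-rule area.
#'
#' @param labels true 0/1 labels (1 positive).
#' @param scores classifier scores for the positive class.
#' @return list with \code{points} (data.frame \code{fpr}, \code{tpr})
#'   and \code{auc}.
#' @export
rocCurve <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("ROC needs both classes present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) sum(scores >= s & labels == 1) / nPos,
                numeric(1))
  fpr <- vapply(thr, function(s) sum(scores >= s & labels == 0) / nNeg,
                numeric(1))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- unique(pts)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

#' Permutation-sampling Shapley feature attribution
#'
#' Model-agnostic Monte-Carlo estimate of Shapley values for the input
#' features of a sequence classifier. The value function is the
#' predicted fatigued-class probability; absent features are replaced by
#' their background mean (over all sequences and time steps). Each draw
#' picks an evaluation sequence and a random feature ordering and
#' accumulates the telescoping marginal contributions.
#'
#' @param classifier an object with a \code{\link{predictProb}} method,
#'   or a function mapping a list of sequence matrices to a numeric
#'   score per sequence.
#' @param dataset a \linkS4class{LabeledDataset} (or list of sequences).
#' @param nSamples number of Monte-Carlo permutations (>= 10).
#' @param seed RNG seed.
#' @return named vector of mean |Shapley value| per feature, named by
#'   the dataset's feature names.
#' @export
shapleyAttribution <- function(classifier, dataset, nSamples = 200L,
                               seed = 1L) {
  if (nSamples < 10L)
    stop("nSamples must be at least 10", call. = FALSE)
  seqs <- if (is(dataset, "LabeledDataset")) sequences(dataset)
          else dataset
  fn <- if (is(dataset, "LabeledDataset")) dataset@featureNames
        else paste0("f", seq_len(ncol(seqs[[1]])))
  nF <- ncol(seqs[[1]])
  score <- if (is.function(classifier)) classifier
           else function(ss) predictProb(classifier, ss)$prob[, 2]
  bg <- colMeans(do.call(rbind, seqs))
  phi <- matrix(0, nSamples, nF)
  withSeed(seed, {
    pickSeq <- sample.int(length(seqs), nSamples, replace = TRUE)
    for (s in seq_len(nSamples)) {
      x <- seqs[[pickSeq[s]]]
      ord <- sample.int(nF)
      # chain of inputs revealing one more feature at each step
      cur <- matrix(bg, nrow(x), nF, byrow = TRUE)
      chain <- vector("list", nF + 1L)
      chain[[1L]] <- cur
      for (j in seq_len(nF)) {
        cur[, ord[j]] <- x[, ord[j]]
        chain[[j + 1L]] <- cur
      }
      v <- score(chain)
      phi[s, ord] <- diff(v)
    }
  })
  out <- colMeans(abs(phi))
  names(out) <- fn
  out
}

## Exact Friedman null distribution (no ties) by dynamic programming over
## per-row rank permutations; returns P(T >= observed).
friedmanExactP <- function(rankSums, n, k) {
  perms <- permutations(k)
  states <- new.env(hash = TRUE)
  assign(paste(rep(0L, k), collapse = ","), 1, envir = states)
  for (row in seq_len(n)) {
    nxt <- new.env(hash = TRUE)
    for (key in ls(states)) {
      cnt <- get(key, envir = states)
      cur <- as.integer(strsplit(key, ",")[[1]])
      for (p in seq_len(nrow(perms))) {
        nk <- paste(cur + perms[p, ], collapse = ",")
        prev <- if (exists(nk, envir = nxt)) get(nk, envir = nxt) else 0
        assign(nk, prev + cnt, envir = nxt)
      }
    }
    states <- nxt
  }
  stat <- function(Rs) 12 / (n * k * (k + 1)) * sum(Rs^2) - 3 * n * (k + 1)
  obs <- stat(rankSums)
  tot <- 0; ge <- 0
  for (key in ls(states)) {
    cnt <- get(key, envir = states)
    Rs <- as.integer(strsplit(key, ",")[[1]])
    tot <- tot + cnt
    if (stat(Rs) >= obs - 1e-9) ge <- ge + cnt
  }
  ge / tot
}

permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    ins <- cbind(sub[, seq_len(i - 1L), drop = FALSE], k,
                 sub[, seq(i, k - 1L)[seq_len(k - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

#' Friedman test with Nemenyi post-hoc comparisons
#'
#' Rank-based comparison of models over matched blocks (rows:
#' folds/muscles/datasets; columns: models). For small untied tables
#' (k <= 4, n <= 12) the p-value is exact, computed from the full
#' permutation null by dynamic programming; otherwise the chi-square
#' approximation is used. When the Friedman test is significant at
#' \code{alpha}, pairwise Nemenyi comparisons based on the studentized
#' range are reported.
#'
#' @param scoreTable numeric matrix, blocks x models.
#' @param alpha significance level for the post-hoc step.
#' @return list with \code{statistic}, \code{p.value}, \code{method},
#'   \code{meanRanks}, and (when significant) \code{nemenyi}: a
#'   data.frame of pairwise rank differences, p-values and significance
#'   flags, plus the critical difference \code{cd}.
#' @examples
#' tab <- cbind(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
#' friedmanNemenyi(tab)
#' @export
friedmanNemenyi <- function(scoreTable, alpha = 0.05) {
  X <- as.matrix(scoreTable)
  n <- nrow(X); k <- ncol(X)
  if (k < 2 || n < 2) stop("need at least 2 models and 2 blocks",
                           call. = FALSE)
  R <- t(apply(X, 1, rank))
  rankSums <- colSums(R)
  if (all(apply(X, 1, function(r) length(unique(r)) == 1))) {
    stat <- 0; p <- 1; method <- "degenerate (all blocks fully tied)"
  } else {
    stat <- 12 / (n * k * (k + 1)) * sum(rankSums^2) - 3 * n * (k + 1)
    hasTies <- any(apply(X, 1, function(r) anyDuplicated(r) > 0))
    if (!hasTies && k <= 4 && n <= 12) {
      p <- friedmanExactP(rankSums, n, k)
      method <- "exact permutation null"
    } else {
      # tie-corrected chi-square approximation
      tieC <- sum(apply(X, 1, function(r) {
        t <- table(r); sum(t^3 - t)
      }))
      denom <- 1 - tieC / (n * k * (k^2 - 1))
      stat <- if (denom > 0) stat / denom else 0
      p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
      method <- "chi-square approximation"
    }
  }
  meanRanks <- rankSums / n
  out <- list(statistic = stat, p.value = p, method = method,
              meanRanks = meanRanks)
  if (p < alpha) {
    se <- sqrt(k * (k + 1) / (12 * n))  # SE of a mean-rank difference
    pairs <- utils::combn(k, 2)
    diffs <- abs(meanRanks[pairs[1, ]] - meanRanks[pairs[2, ]])
    pvals <- ptukey(diffs / se, k, Inf, lower.tail = FALSE)
    cd <- stats::qtukey(1 - alpha, k, Inf) * se
    out$nemenyi <- data.frame(
      i = pairs[1, ], j = pairs[2, ], rankDiff = diffs,
      p.value = pvals, significant = pvals < alpha)
    out$cd <- cd
  }
  out
}

#' Evaluate a classifier on a labelled dataset
#'
#' @param model a trained classifier with a \code{\link{predictProb}}
#'   method.
#' @param dataset a \linkS4class{LabeledDataset}.
#' @param foldMetrics optional data.frame of per-fold metrics (columns
#'   acc, pre, recall, f1) used for the mean +/- SD report.
#' @param attribution optional precomputed attribution scores.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateClassifier <- function(model, dataset, foldMetrics = NULL,
                               attribution = numeric(0)) {
  pred <- predictProb(model, dataset)
  y <- labels2(dataset)
  cc <- confusionCounts(y, pred$label)
  m <- classificationMetrics(cc)
  roc <- rocCurve(y, pred$prob[, 2])
  if (is.null(foldMetrics)) {
    metrics <- data.frame(metric = c("acc", "pre", "recall", "f1"),
                          mean = c(m$acc, m$pre, m$recall, m$f1),
                          sd = NA_real_)
  } else {
    metrics <- data.frame(
      metric = c("acc", "pre", "recall", "f1"),
      mean = c(mean(foldMetrics$acc), mean(foldMetrics$pre),
               mean(foldMetrics$recall), mean(foldMetrics$f1)),
      sd = c(sd(foldMetrics$acc), sd(foldMetrics$pre),
             sd(foldMetrics$recall), sd(foldMetrics$f1)))
  }
  new("EvalReport", counts = cc, metrics = metrics,
      rocPoints = roc$points, auc = roc$auc,
      attribution = attribution, comparisonTests = list())
}
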