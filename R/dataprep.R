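## Dataset preparation: feature normalisation, equal-length resampling,
## window labelling and split plans.

#' Min-max normalisation of feature columns
#'
#' Maps each feature column to [0, 1] using the column minimum and
#' maximum. With \code{scope = "per_trial"} the bounds come from the data
#' itself; with \code{scope = "train_set"} previously stored bounds are
#' applied and out-of-range values are clipped into [0, 1] (their count
#' is reported via a message). Constant columns map to 0 with a warning.
#'
#' @param x numeric matrix (windows x features).
#' @param scope \code{"per_trial"} (fit bounds on \code{x}) or
#'   \code{"train_set"} (reuse \code{bounds}).
#' @param bounds list with \code{min} and \code{max} vectors, required
#'   when \code{scope = "train_set"}.
#' @return list with \code{x} (normalised matrix) and \code{bounds}.
#' @examples
#' minMaxNormalize(cbind(f = c(2, 4, 6)))$x
#' @export
minMaxNormalize <- function(x, scope = c("per_trial", "train_set"),
                            bounds = NULL) {
  scope <- match.arg(scope)
  x <- as.matrix(x)
  if (length(x) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(x[!is.na(x)])))
    stop("non-finite feature values", call. = FALSE)
  if (scope == "per_trial") {
    bounds <- list(min = apply(x, 2, min, na.rm = TRUE),
                   max = apply(x, 2, max, na.rm = TRUE))
  } else if (is.null(bounds)) {
    stop("train_set scope requires stored bounds", call. = FALSE)
  }
  rng <- bounds$max - bounds$min
  const <- rng == 0
  if (scope == "per_trial" && any(const))
    warning(sprintf("constant feature(s) mapped to 0: %s",
                    paste(colnames(x)[const], collapse = ", ")))
  rng[const] <- 1
  out <- sweep(sweep(x, 2, bounds$min, "-"), 2, rng, "/")
  out[, const] <- 0
  nClip <- sum(out < 0 | out > 1, na.rm = TRUE)
  if (nClip > 0) {
    message(sprintf("%d value(s) outside stored bounds clipped to [0, 1]",
                    nClip))
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  list(x = out, bounds = bounds)
}

#' Equal-length resampling of a feature-row sequence
#'
#' Brings a \code{T x F} block to exactly \code{targetLen} rows. Excess
#' rows are removed at evenly spaced positions
#' (\code{round(j * T / nDrop)} for j = 1..nDrop, deduplicated); missing
#' rows are filled by duplicating the preceding row at evenly spaced
#' slots, preserving relative order and continuity.
#'
#' @param seq numeric matrix, rows ordered in time.
#' @param targetLen desired row count (>= 2).
#' @return matrix with \code{targetLen} rows.
#' @examples
#' equalizeLength(rbind(a = 1:3, b = 4:6), 4)
#' @export
equalizeLength <- function(seq, targetLen) {
  seq <- as.matrix(seq)
  if (targetLen < 2) stop("targetLen must be >= 2", call. = FALSE)
  tLen <- nrow(seq)
  if (tLen == targetLen) return(seq)
  if (tLen > targetLen) {
    nDrop <- tLen - targetLen
    drop <- unique(pmin(tLen, pmax(1L, round(seq_len(nDrop) * tLen / nDrop))))
    # deduplication can under-drop; remove further evenly spaced rows
    while (tLen - length(drop) > targetLen) {
      cand <- setdiff(seq_len(tLen), drop)
      drop <- c(drop, cand[round(length(cand) / 2)])
    }
    return(seq[-drop, , drop = FALSE])
  }
  nIns <- targetLen - tLen
  # duplicate the row at evenly spaced source positions; each inserted
  # row copies its predecessor
  pos <- pmax(1L, pmin(tLen, round(seq_len(nIns) * tLen / nIns)))
  reps <- 1L + tabulate(pos, nbins = tLen)
  out <- seq[rep(seq_len(tLen), times = reps), , drop = FALSE]
  # rounding collisions can over-insert; trim duplicates from the end
  if (nrow(out) > targetLen)
    out <- out[seq_len(targetLen), , drop = FALSE]
  while (nrow(out) < targetLen)
    out <- rbind(out, out[nrow(out), , drop = FALSE])
  out
}

#' Label windows from ground truth or fractional scheme
#'
#' Simulated data: windows whose centre falls in the relaxed span get 0,
#' in the fatigued span get 1, others NA (excluded transition). Real
#' data: the first \code{p0} fraction of the recording span is relaxed,
#' the last \code{p1} fatigued.
#'
#' @param windowTimes window-centre times in seconds.
#' @param truth optional \linkS4class{SimGroundTruth}; when NULL the
#'   fractional scheme is used over \code{range(windowTimes)}.
#' @param p0,p1 relaxed / fatigued fractions for the fractional scheme.
#' @return integer vector of 0 / 1 / NA labels.
#' @export
assignLabels <- function(windowTimes, truth = NULL, p0 = 0.3, p1 = 0.3) {
  if (is.null(truth)) {
    if (p0 + p1 > 1) stop("p0 + p1 must not exceed 1", call. = FALSE)
    lo <- min(windowTimes); hi <- max(windowTimes)
    span <- hi - lo
    rel <- c(lo, lo + p0 * span)
    fat <- c(hi - p1 * span, hi)
  } else {
    rel <- truth@labelBoundaries$relaxed
    fat <- truth@labelBoundaries$fatigued
  }
  lab <- rep(NA_integer_, length(windowTimes))
  lab[windowTimes >= rel[1] & windowTimes <= rel[2]] <- 0L
  lab[windowTimes >= fat[1] & windowTimes <= fat[2]] <- 1L
  lab
}

#' Build fixed-length sub-sequences from labelled windows
#'
#' Groups consecutive same-label windows into overlapping sub-sequences
#' of \code{len} rows (stride \code{stride}); the sequence label is the
#' (unanimous) window label. Windows labelled NA are excluded.
#'
#' @param fm a \linkS4class{FeatureMatrix} or plain matrix of normalised
#'   window features.
#' @param labels per-window 0/1/NA labels.
#' @param len sub-sequence length in windows (default 16).
#' @param stride hop between sub-sequence starts (default \code{len / 2}).
#' @param group trial identifier attached to every sequence.
#' @return a \linkS4class{LabeledDataset}.
#' @export
buildSequences <- function(fm, labels, len = 16L, stride = len %/% 2L,
                           group = "trial1") {
  vals <- if (is(fm, "FeatureMatrix")) featureValues(fm) else as.matrix(fm)
  stopifnot(length(labels) == nrow(vals))
  seqs <- list(); labs <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    if (!length(idx)) next
    # split into runs of consecutive windows
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    for (run in runs) {
      if (length(run) < len) next
      starts <- seq(1L, length(run) - len + 1L, by = stride)
      for (s0 in starts) {
        seqs[[length(seqs) + 1L]] <- vals[run[s0:(s0 + len - 1L)], ,
                                          drop = FALSE]
        labs <- c(labs, cls)
      }
    }
  }
  labeledDataset(seqs, labs, groups = rep(group, length(seqs)))
}

#' Stratified holdout and cross-validation split plan
#'
#' Draws a stratified \code{testFraction} holdout, then partitions the
#' remaining training indices into \code{nFolds} stratified folds. With
#' \code{groupAware = TRUE} whole groups (trials) are assigned to either
#' train or test so no trial straddles the boundary.
#'
#' @param dataset a \linkS4class{LabeledDataset} (or integer label
#'   vector).
#' @param testFraction holdout fraction (default 0.2).
#' @param nFolds cross-validation folds within the training set.
#' @param seed RNG seed.
#' @param groupAware keep each group wholly in train or test.
#' @return list with \code{trainIdx}, \code{testIdx} and \code{folds}
#'   (list of validation-index vectors partitioning \code{trainIdx}).
#' @export
splitCV <- function(dataset, testFraction = 0.2, nFolds = 5L, seed = 1L,
                    groupAware = FALSE) {
  labels <- if (is(dataset, "LabeledDataset")) labels2(dataset)
            else as.integer(dataset)
  n <- length(labels)
  withSeed(seed, {
    if (groupAware && is(dataset, "LabeledDataset")) {
      g <- groups(dataset)
      ug <- unique(g)
      nTest <- max(1L, round(testFraction * length(ug)))
      testG <- sample(ug, nTest)
      testIdx <- which(g %in% testG)
      trainIdx <- setdiff(seq_len(n), testIdx)
    } else {
      testIdx <- integer(0)
      for (cls in unique(labels)) {
        ci <- which(labels == cls)
        testIdx <- c(testIdx, sample(ci, round(testFraction * length(ci))))
      }
      testIdx <- sort(testIdx)
      trainIdx <- setdiff(seq_len(n), testIdx)
    }
    folds <- vector("list", nFolds)
    for (cls in unique(labels[trainIdx])) {
      ci <- sample(trainIdx[labels[trainIdx] == cls])
      assign0 <- rep(seq_len(nFolds), length.out = length(ci))
      for (f in seq_len(nFolds))
        folds[[f]] <- c(folds[[f]], ci[assign0 == f])
    }
    folds <- lapply(folds, sort)
  })
  list(trainIdx = trainIdx, testIdx = testIdx, folds = folds)
}

#' Subset a LabeledDataset
#' @param dataset a \linkS4class{LabeledDataset}.
#' @param idx sequence indices to keep.
#' @return the subsetted \linkS4class{LabeledDataset}.
#' @export
subsetDataset <- function(dataset, idx) {
  labeledDataset(sequences(dataset)[idx], labels2(dataset)[idx],
                 groups(dataset)[idx], dataset@featureNames)
}
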