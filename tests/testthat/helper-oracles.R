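## Independent oracles used to cross-check the package implementations.

## Brute-force O(N^2) sample entropy: explicit double loop over template
## pairs, Chebyshev distance, self-matches excluded, pairs counted once.
bruteSampEn <- function(x, m = 2L, rFrac = 0.2) {
  N <- length(x)
  r <- rFrac * sd(x)
  nt <- N - m
  B <- 0L; A <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r) {
        B <- B + 1L
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1L
      }
    }
  }
  if (B == 0L) return(0)
  if (A == 0L) return(log(nt * (nt - 1) / 2))
  -log(A / B)
}

## Monte-Carlo permutation reference for the Friedman test (no ties):
## permutes values within each block independently.
permFriedmanP <- function(X, nPerm = 4000L, seed = 1L) {
  n <- nrow(X); k <- ncol(X)
  statOf <- function(M) {
    Rs <- colSums(t(apply(M, 1, rank)))
    12 / (n * k * (k + 1)) * sum(Rs^2) - 3 * n * (k + 1)
  }
  obs <- statOf(X)
  set.seed(seed)
  cnt <- 0L
  for (p in seq_len(nPerm)) {
    Xp <- t(apply(X, 1, sample))
    if (statOf(Xp) >= obs - 1e-9) cnt <- cnt + 1L
  }
  cnt / nPerm
}

## Small linearly separable sequence dataset (two Gaussian classes).
makeSeparableDataset <- function(n = 120L, T = 16L, F = 8L, gap = 1.5,
                                 seed = 1L) {
  set.seed(seed)
  labs <- rep(0:1, length.out = n)
  seqs <- lapply(seq_len(n), function(i)
    matrix(rnorm(T * F, mean = gap * labs[i]), T, F))
  labeledDataset(seqs, labs)
}

## Fast model configuration for tests.
testModelConfig <- function(seed = 1L, epochs = 20L)
  modelConfig(dModel = 16L, nHeads = 2L, nLayers = 1L, ffDim = 32L,
              epochs = epochs, seed = seed)

## Default-condition simulated dataset from the top planted channel.
simDataset <- function(nTrials = 2L, duration = 40, seed = 1L,
                       channel = 1L) {
  ds <- lapply(seq_len(nTrials), function(i) {
    tr <- generateTrial(simConfig(duration = duration,
                                  seed = seed * 100 + i))
    trialDataset(tr, channel, group = paste0("trial", i))
  })
  mergeDatasets(ds)
}
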