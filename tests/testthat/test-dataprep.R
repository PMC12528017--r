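test_that("min-max normalisation maps to [0,1] and guards degeneracies", {
  out <- minMaxNormalize(cbind(f = c(2, 4, 6)))
  expect_equal(out$x[, 1], c(0, 0.5, 1))
  expect_warning(cst <- minMaxNormalize(cbind(f = c(5, 5, 5))), "constant")
  expect_equal(cst$x[, 1], c(0, 0, 0))
  # idempotence at per-trial scope
  once <- minMaxNormalize(cbind(a = rnorm(20), b = runif(20)))$x
  expect_equal(minMaxNormalize(once)$x, once, tolerance = 1e-12)
  # train-set scope clips out-of-range values
  tr <- minMaxNormalize(cbind(f = c(0, 10)))
  expect_message(
    te <- minMaxNormalize(cbind(f = c(-5, 5, 15)), scope = "train_set",
                          bounds = tr$bounds),
    "clipped")
  expect_equal(te$x[, 1], c(0, 0.5, 1))
  expect_error(minMaxNormalize(matrix(numeric(0), 0, 0)), "empty")
})

test_that("equal-length resampling enumerated cases and exactness", {
  m <- matrix(1:8, 4, 2)
  expect_identical(equalizeLength(m, 4), m)
  ab <- rbind(c(1, 10), c(2, 20))
  expect_equal(equalizeLength(ab, 4),
               rbind(c(1, 10), c(1, 10), c(2, 20), c(2, 20)))
  m6 <- matrix(c(1:6, 11:16), 6, 2)
  out <- equalizeLength(m6, 4)
  expect_equal(nrow(out), 4L)
  expect_equal(out[1, ], m6[1, ])               # first row kept
  expect_true(all(out[, 1] %in% m6[, 1]))       # subsequence of input
  expect_true(all(diff(match(out[, 1], m6[, 1])) > 0))  # order preserved
  expect_error(equalizeLength(m, 1), "targetLen")
  # exact output length for any input length
  for (tl in c(1, 2, 3, 7, 16, 30))
    for (target in c(2, 5, 16))
      expect_equal(nrow(equalizeLength(matrix(seq_len(2 * tl), tl), target)),
                   target)
})

test_that("label assignment follows boundaries and fractions", {
  tr <- generateTrial(simConfig(duration = 10, seed = 1))
  times <- seq(0.25, 9.75, by = 0.5)
  lab <- assignLabels(times, groundTruth(tr))
  expect_true(all(lab[times <= 3] == 0, na.rm = FALSE))
  expect_true(all(lab[times >= 7] == 1))
  expect_true(all(is.na(lab[times > 3 & times < 7])))
  # fractional scheme on a symmetric grid balances classes within one
  lab2 <- assignLabels(seq(0, 100, by = 1))
  expect_lte(abs(sum(lab2 == 0, na.rm = TRUE) -
                 sum(lab2 == 1, na.rm = TRUE)), 1)
  expect_error(assignLabels(times, p0 = 0.6, p1 = 0.5), "exceed")
})

test_that("sequence building groups consecutive same-label windows", {
  vals <- matrix(seq_len(200 * 3), 200, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  labels <- c(rep(0L, 60), rep(NA, 80), rep(1L, 60))
  ds <- buildSequences(vals, labels, len = 16L, stride = 8L)
  expect_s4_class(ds, "LabeledDataset")
  expect_true(all(vapply(sequences(ds), nrow, integer(1)) == 16L))
  # runs of 60 windows give floor((60-16)/8)+1 = 6 sequences per class
  expect_equal(sum(labels2(ds) == 0), 6L)
  expect_equal(sum(labels2(ds) == 1), 6L)
  # sequences never span the excluded transition
  expect_true(all(vapply(sequences(ds), function(s)
    all(diff(s[, 1]) == 1), logical(1))))
})

test_that("split plans are stratified, disjoint and reproducible", {
  labs <- rep(c(0L, 1L), each = 50)
  sp <- splitCV(labs, testFraction = 0.2, nFolds = 5, seed = 4)
  expect_length(sp$testIdx, 20L)
  expect_length(intersect(sp$trainIdx, sp$testIdx), 0L)
  expect_setequal(unlist(sp$folds), sp$trainIdx)
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(sp$folds[[i]], sp$folds[[j]]), 0L)
  expect_identical(sp, splitCV(labs, testFraction = 0.2, nFolds = 5,
                               seed = 4))
  # group-aware: no trial straddles train/test
  ds <- makeSeparableDataset(n = 40)
  ds@groups <- rep(paste0("t", 1:8), each = 5)
  spg <- splitCV(ds, groupAware = TRUE, seed = 2)
  gTest <- unique(groups(ds)[spg$testIdx])
  gTrain <- unique(groups(ds)[spg$trainIdx])
  expect_length(intersect(gTest, gTrain), 0L)
})
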