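test_that("confusion counts are order-invariant and complete", {
  expect_equal(confusionCounts(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               c(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  expect_equal(confusionCounts(c(1, 0), c(0, 1)),
               c(tp = 0L, tn = 0L, fp = 1L, fn = 1L))
  set.seed(1)
  y <- rbinom(50, 1, 0.5); p <- rbinom(50, 1, 0.5)
  o <- sample(50)
  expect_equal(confusionCounts(y, p), confusionCounts(y[o], p[o]))
  expect_equal(sum(confusionCounts(y, p)), 50L)
})

test_that("metrics reproduce the closed-form identities", {
  m <- classificationMetrics(50, 40, 10, 0)
  expect_equal(m$acc, 0.9)
  expect_equal(m$pre, 50 / 60)
  expect_equal(round(m$pre, 4), 0.8333)
  expect_equal(m$recall, 1)
  expect_equal(round(m$f1, 4), 0.9091)
  p <- classificationMetrics(7, 13, 0, 0)
  expect_equal(unlist(p[c("acc", "pre", "recall", "f1")]),
               c(acc = 1, pre = 1, recall = 1, f1 = 1))
  expect_warning(u <- classificationMetrics(0, 10, 0, 5), "undefined")
  expect_equal(u$pre, 0)
  expect_true("pre" %in% u$undefined)
  # metrics . confusion reproduces plain accuracy
  set.seed(2)
  y <- rbinom(80, 1, 0.4); pr <- rbinom(80, 1, 0.6)
  m2 <- suppressWarnings(classificationMetrics(confusionCounts(y, pr)))
  expect_equal(m2$acc, mean(y == pr))
})

test_that("ROC/AUC sweep matches its invariants and an external check", {
  y <- c(rep(0, 5), rep(1, 5))
  sep <- c(runif(5, 0, 0.4), runif(5, 0.6, 1))
  expect_equal(rocCurve(y, sep)$auc, 1)
  r <- rocCurve(y, sep)
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  expect_equal(tail(r$points$fpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  # chance level on label-independent scores
  for (s in 1:10) {
    set.seed(s)
    yy <- rbinom(2000, 1, 0.5); ss <- runif(2000)
    a <- rocCurve(yy, ss)$auc
    expect_gte(a, 0.45); expect_lte(a, 0.55)
  }
  # symmetry
  set.seed(3)
  yy <- rbinom(200, 1, 0.5); ss <- rnorm(200)
  expect_equal(rocCurve(yy, ss)$auc + rocCurve(yy, -ss)$auc, 1)
  # agreement with pROC
  skip_if_not_installed("pROC")
  auc2 <- as.numeric(pROC::auc(pROC::roc(yy, ss, quiet = TRUE,
                                         direction = "<")))
  expect_equal(rocCurve(yy, ss)$auc, auc2, tolerance = 1e-9)
  expect_error(rocCurve(rep(1, 5), runif(5)), "both classes")
})

test_that("Shapley attribution recovers known structure", {
  set.seed(5)
  T <- 4L; F <- 4L
  seqs <- lapply(1:40, function(i) matrix(rnorm(T * F), T, F))
  ds <- labeledDataset(seqs, rep(0:1, 20),
                       featureNames = paste0("f", 1:F))
  # linear scorer over sequence means; feature 4 is ignored
  coefs <- c(3, -2, 0.5, 0)
  scorer <- function(ss) vapply(ss, function(s)
    sum(colMeans(s) * coefs), numeric(1))
  phi <- shapleyAttribution(scorer, ds, nSamples = 400, seed = 1)
  expect_lt(phi["f4"], 0.05 * max(phi))
  # ranking matches |coef| x SD ranking (all features have SD ~ equal)
  expect_equal(order(-phi[1:3]), order(-abs(coefs[1:3])))
  # duplicated features share credit equally (within MC tolerance)
  scorer2 <- function(ss) vapply(ss, function(s)
    colMeans(s)[1] + colMeans(s)[2], numeric(1))
  seqs2 <- lapply(seqs, function(s) { s[, 2] <- s[, 1]; s })
  ds2 <- labeledDataset(seqs2, rep(0:1, 20),
                        featureNames = paste0("f", 1:F))
  phi2 <- shapleyAttribution(scorer2, ds2, nSamples = 600, seed = 2)
  expect_lt(abs(phi2["f1"] - phi2["f2"]) / max(phi2), 0.10)
  expect_error(shapleyAttribution(scorer, ds, nSamples = 5), "at least 10")
})

test_that("Friedman test handles ties, dominance and matches permutation", {
  same <- matrix(rep(c(1, 2, 3), 3), 3, 3)
  res <- friedmanNemenyi(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  # one model strictly best on every one of 12 rows (k = 3)
  set.seed(6)
  base <- matrix(runif(24, 0.6, 0.8), 12, 2)
  tab <- cbind(best = apply(base, 1, max) + runif(12, 0.05, 0.1), base)
  res2 <- friedmanNemenyi(tab)
  expect_lt(res2$p.value, 0.05)
  expect_true(!is.null(res2$nemenyi))
  expect_true(any(res2$nemenyi$significant))
  # exact p agrees with a Monte-Carlo permutation reference
  for (s in 1:3) {
    set.seed(s + 20)
    X <- matrix(rnorm(30), 10, 3)
    pExact <- friedmanNemenyi(X)$p.value
    pPerm <- permFriedmanP(X, nPerm = 4000, seed = s)
    expect_lt(abs(pExact - pPerm), 0.02)
  }
})

test_that("classifier evaluation assembles a coherent report", {
  ds <- makeSeparableDataset(n = 60)
  mod <- trainXGBoost(ds, testModelConfig())
  rep <- evaluateClassifier(mod, ds)
  expect_s4_class(rep, "EvalReport")
  expect_equal(sum(rep@counts), 60)
  expect_true(all(rep@metrics$mean >= 0 & rep@metrics$mean <= 1))
  expect_gte(rep@auc, 0.95)
})
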