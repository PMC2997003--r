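test_that("stratified folds balance both classes to within one sequence", {
  set.seed(20)
  ds <- labeledProteinSet(
    setNames(vapply(1:234, function(i) randSeq(30), character(1)),
             paste0("s", 1:234)),
    rep(c(1L, 0L), each = 117))
  folds <- makeFolds(ds, 5, seed = 3)
  expect_setequal(names(folds), sequenceIDs(ds))
  lab <- classLabels(ds)
  posPerFold <- table(folds[lab == 1L])
  negPerFold <- table(folds[lab == 0L])
  expect_true(all(posPerFold %in% c(23L, 24L)))
  expect_true(all(negPerFold %in% c(23L, 24L)))

  small <- ds[c(1:5, 118:122)]
  f5 <- makeFolds(small, 5, seed = 1)
  expect_true(all(table(f5, classLabels(small)[names(f5)]) == 1L))

  expect_identical(makeFolds(ds, 5, seed = 9), makeFolds(ds, 5, seed = 9))
  expect_error(makeFolds(ds[1:10], 5), "at least k")
})

test_that("confusion tallies match hand counts and a brute-force oracle", {
  expect_identical(confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1)),
                   c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  expect_identical(confusionCounts(c(1, 0, 1), c(1, 0, 1)),
                   c(TP = 2L, TN = 1L, FP = 0L, FN = 0L))
  expect_error(confusionCounts(c(1, 0), c(1)), "equal length")
  set.seed(22)
  for (rep in 1:20) {
    y <- sample(0:1, 50, replace = TRUE)
    p <- sample(0:1, 50, replace = TRUE)
    expect_identical(confusionCounts(y, p), bruteConfusion(y, p))
  }
})

test_that("the metric engine reproduces the published independent-set sweep", {
  ## counts back-solved from the printed sensitivity/specificity at
  ## 44 positives / 450 negatives must reproduce the printed accuracy
  ## and MCC of every row to 2-decimal rounding
  sweep <- independentSetSweep()
  for (i in seq_len(nrow(sweep))) {
    counts <- backSolveCounts(sweep$sensitivity[i], sweep$specificity[i],
                              44, 450)
    m <- classMetrics(counts)
    expect_equal(round(m[["sensitivity"]], 2), sweep$sensitivity[i])
    expect_equal(round(m[["specificity"]], 2), sweep$specificity[i])
    expect_equal(round(m[["accuracy"]], 2), sweep$accuracy[i],
                 info = sprintf("threshold %.1f", sweep$threshold[i]))
    expect_equal(round(m[["mcc"]], 2), sweep$mcc[i],
                 info = sprintf("threshold %.1f", sweep$threshold[i]))
  }
})

test_that("metric edge cases: perfection, undefined denominators, MCC bounds", {
  m <- classMetrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(m[["mcc"]], 1)
  expect_equal(m[["accuracy"]], 100)

  ## no positives in truth: sensitivity undefined, not zero
  m <- classMetrics(c(TP = 0, TN = 5, FP = 3, FN = 0))
  expect_true(is.na(m[["sensitivity"]]))
  expect_false(is.na(m[["specificity"]]))
  ## zero MCC denominator collapses to 0 by convention
  expect_identical(m[["mcc"]], 0)

  set.seed(23)
  for (rep in 1:50) {
    counts <- setNames(as.numeric(sample(0:30, 4, replace = TRUE)),
                       c("TP", "TN", "FP", "FN"))
    if (sum(counts) == 0) next
    mcc <- classMetrics(counts)[["mcc"]]
    expect_gte(mcc, -1); expect_lte(mcc, 1)
  }
  expect_error(classMetrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
})

test_that("cross-validation separates signal, not shuffled labels", {
  g <- generateDataset(generatorConfig(
    nPerClass = c(40L, 40L), lengthRange = c(150L, 250L),
    biasedDipeptides = list(positive = c(GR = 5, ND = 5, MV = 5),
                            negative = numeric(0))), seed = 33)
  cfg <- pipelineConfig("dpc-selected", "stage1",
                        dipeptides = c("GR", "ND", "MV"))
  r <- crossValidate(g$dataset, cfg, seed = 33)
  expect_equal(r$mean[["accuracy"]], 100)

  ## permutation null: shuffle labels, expect chance-level MCC
  shuffled <- withr::with_seed(34, labeledProteinSet(
    sequences(g$dataset), sample(classLabels(g$dataset))))
  rn <- crossValidate(shuffled, cfg, seed = 34)
  expect_lt(abs(rn$mean[["mcc"]]), 0.35)

  r2 <- crossValidate(g$dataset, cfg, seed = 33)
  expect_identical(r$perFold, r2$perFold)
  expect_identical(r$decisionValues, r2$decisionValues)
})

test_that("per-fold mean and pooled-count summaries are both reported", {
  g <- generateDataset(generatorConfig(
    nPerClass = c(25L, 25L), lengthRange = c(100L, 150L),
    biasedDipeptides = list(positive = c(GR = 6), negative = numeric(0))),
    seed = 35)
  r <- crossValidate(g$dataset, pipelineConfig("dpc-selected", "stage1",
                                               dipeptides = "GR"),
                     seed = 35)
  expect_identical(nrow(r$perFold), 5L)
  expect_identical(sum(r$pooledCounts), 50L)
  expect_named(r$mean, c("sensitivity", "specificity", "accuracy", "mcc"))
  expect_named(r$pooled, c("sensitivity", "specificity", "accuracy", "mcc"))
})

test_that("threshold sweeps are ordered, monotone and cover the grid", {
  withr::with_seed(26, {
    X <- matrix(rnorm(300), 150, 2, dimnames = list(NULL, c("a", "b")))
    y <- as.integer(X[, 1] + rnorm(150, 0, 0.8) > 0)
    m <- trainSVM(X, y)
    sw <- thresholdSweep(m, X, y)
    expect_identical(nrow(sw), 21L)
    expect_equal(sw$threshold, seq(-1, 1, by = 0.1))
    expect_true(all(diff(sw$sensitivity) <= 1e-9))
    expect_true(all(diff(sw$specificity) >= -1e-9))
    ## below every decision value everything is predicted positive
    dv <- decisionValues(m, X)
    low <- sweepFromScores(dv, y, min(dv) - 1)
    expect_equal(low$sensitivity, 100)
    expect_equal(low$specificity, 0)
    expect_error(thresholdSweep(m, X, y, numeric(0)), "non-empty")
  })
})

test_that("ROC behaves at the extremes and under polarity reversal", {
  sep <- rocCurve(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1)
  expect_equal(utils::tail(sep$points, 1)$tpr, 1)
  expect_equal(sep$points$fpr[1], 0)

  withr::with_seed(27, {
    scores <- rnorm(2000)
    labels <- sample(0:1, 2000, replace = TRUE)
    null <- rocCurve(scores, labels)
    expect_lt(abs(null$auc - 0.5), 0.05)
    flip <- rocCurve(scores, 1 - labels)
    expect_equal(flip$auc, 1 - null$auc, tolerance = 1e-12)
  })
  expect_error(rocCurve(1:5, rep(1, 5)), "both classes")
})

test_that("ROC area equals the normalized Mann-Whitney statistic", {
  withr::with_seed(28, {
    for (rep in 1:5) {
      n <- sample(20:200, 1)
      labels <- sample(0:1, n, replace = TRUE, prob = c(0.6, 0.4))
      if (length(unique(labels)) < 2) next
      scores <- rnorm(n) + labels  # ties possible after rounding
      scores <- round(scores, 1)
      expect_equal(rocCurve(scores, labels)$auc,
                   mannWhitneyAUC(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(29, {
    scores <- round(rnorm(300), 1)
    labels <- as.integer(scores + rnorm(300) > 0)
    ours <- rocCurve(scores, labels)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-12)
  })
})

test_that("presentation rounding is 2 decimals and TSV export mirrors it", {
  m <- classMetrics(c(TP = 23, TN = 450, FP = 0, FN = 21))
  pm <- presentMetrics(m)
  expect_equal(pm[["accuracy"]], 95.75)
  expect_equal(pm[["mcc"]], 0.71)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeReportTSV(data.frame(threshold = 0, t(m)), f)
  back <- read.delim(f)
  expect_equal(back$accuracy, 95.75)
})
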