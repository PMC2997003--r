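test_that("simple-mode local alignment matches hand-computed scores", {
  p <- alignmentParams(match = 2, mismatch = -1, gapOpen = 2, gapExtend = 1)
  expect_equal(localAlignScore("HIGH", "HIGH", p), 8)
  expect_equal(swOracle("HIGH", "HIGH", simpleSubMat(), 2, 1), 8)
  expect_equal(localAlignScore("AAAA", "CCCC", p), 0)
  ## a gap-requiring pair, checked against the DP oracle
  expect_equal(localAlignScore("ACDEF", "ACEF", p),
               swOracle("ACDEF", "ACEF", simpleSubMat(), 2, 1))
})

test_that("alignment scores are symmetric", {
  p <- alignmentParams(match = 2, mismatch = -1, gapOpen = 2, gapExtend = 1)
  b <- alignmentParams()
  set.seed(41)
  for (rep in 1:100) {
    a <- randSeq(sample(3:25, 1))
    bseq <- randSeq(sample(3:25, 1))
    expect_equal(localAlignScore(a, bseq, p), localAlignScore(bseq, a, p))
    if (rep <= 20)
      expect_equal(localAlignScore(a, bseq, b), localAlignScore(bseq, a, b))
  }
})

test_that("aligner agrees with the Gotoh oracle on short pairs", {
  sub4 <- c("A", "C", "D", "E")
  simple <- alignmentParams(match = 2, mismatch = -1, gapOpen = 2,
                            gapExtend = 1)
  blosum <- alignmentParams()
  sm <- simpleSubMat()
  bm <- blosum$substitutionMatrix
  ## exhaustive over all pairs of length <= 2 strings
  short <- unlist(lapply(1:2, function(L)
    apply(do.call(expand.grid, rep(list(sub4), L)), 1, paste, collapse = "")))
  for (a in short) for (b in short) {
    expect_equal(localAlignScore(a, b, simple), swOracle(a, b, sm, 2, 1),
                 info = paste(a, b))
  }
  ## random sample of longer pairs (lengths 3-6), both scoring schemes
  set.seed(43)
  for (rep in 1:150) {
    a <- randSeq(sample(3:6, 1), sub4)
    b <- randSeq(sample(3:6, 1), sub4)
    expect_equal(localAlignScore(a, b, simple), swOracle(a, b, sm, 2, 1),
                 info = paste("simple", a, b))
    expect_equal(localAlignScore(a, b, blosum),
                 swOracle(a, b, bm, 11, 1), info = paste("blosum", a, b))
  }
})

test_that("top-hit classification adopts the best hit's label", {
  set.seed(44)
  db <- labeledProteinSet(
    c(p1 = "MKHIGHKMSKSWADE", p2 = "MKHIGHKMSKSWDEA",
      n1 = "ACDCACDCACDCACD", n2 = "EEEDDDEEEDDDEEE"),
    c(1L, 1L, 0L, 0L))
  p <- alignmentParams()
  self <- topHitClassify("MKHIGHKMSKSWADE", db, p)
  expect_identical(self$label, 1L)
  expect_identical(self$hit, "p1")

  ## a random query against an unrelated db with a high threshold: no hit
  p200 <- alignmentParams(threshold = 200)
  miss <- topHitClassify(randSeq(20), db, p200)
  expect_true(is.na(miss$label))

  ## threshold 0 never produces a no-hit
  always <- topHitClassify(randSeq(20), db, alignmentParams(threshold = 0))
  expect_false(is.na(always$label))
  expect_error(topHitClassify("ACDE", db[integer(0)]), "non-empty")
})

test_that("raising the threshold never increases classified queries", {
  set.seed(45)
  db <- labeledProteinSet(
    setNames(vapply(1:10, function(i) randSeq(40), character(1)),
             paste0("d", 1:10)),
    rep(c(1L, 0L), 5))
  queries <- vapply(1:15, function(i) randSeq(40), character(1))
  classified <- vapply(c(0, 10, 20, 40, 80), function(t) {
    p <- alignmentParams(threshold = t)
    sum(!is.na(vapply(queries, function(q)
      topHitClassify(q, db, p)$label, integer(1))))
  }, integer(1))
  expect_true(all(diff(classified) <= 0L))
})

## two synthetic families sharing long class-specific motifs
makeFamilies <- function(seed) {
  generateDataset(generatorConfig(
    nPerClass = c(15L, 15L), lengthRange = c(60L, 90L),
    motifPlan = list(positive = setNames(1, "HIGHKMSKSWWNDAYQKEIE"),
                     negative = setNames(1, "FRAEGYPMCGEWDNMGARKD"))),
    seed = seed)$dataset
}

test_that("similarity CV separates well-separated families", {
  ds <- makeFamilies(46)
  folds <- makeFolds(ds, 5, seed = 46)
  r <- cvSimilarityEval(ds, folds, alignmentParams(threshold = 30))
  expect_gte(r$mean[["accuracy"]], 90)
  ## deterministic for fixed inputs
  r2 <- cvSimilarityEval(ds, folds, alignmentParams(threshold = 30))
  expect_identical(r$perFold, r2$perFold)
})

test_that("no-hit accounting follows the published rule, with a corrected mode", {
  ds <- makeFamilies(47)
  folds <- makeFolds(ds, 5, seed = 47)
  ## threshold above every attainable score: every query is a no-hit;
  ## positives all FN (sensitivity 0) and, as published, negatives all FP
  p <- alignmentParams(threshold = 1e6)
  r <- cvSimilarityEval(ds, folds, p)
  expect_equal(unname(r$pooledCounts),
               c(0L, 0L, 15L, 15L), ignore_attr = TRUE)
  expect_equal(r$pooled[["sensitivity"]], 0)
  expect_equal(r$pooled[["specificity"]], 0)
  rc <- cvSimilarityEval(ds, folds, p, accounting = "corrected")
  expect_equal(rc$pooledCounts[["TN"]], 15L)
  expect_equal(rc$pooled[["specificity"]], 100)
})

test_that("external tabular hits can be ingested", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("q1", "s1", "98.5", "100", "1", "0", "1", "100",
                   "1", "100", "1e-50", "185.3", sep = "\t"), f)
  tab <- readTabularHits(f)
  expect_identical(tab$query, "q1")
  expect_equal(tab$bitscore, 185.3)
  writeLines("q1\ts1", f)
  expect_error(readTabularHits(f), "12-column")
})
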