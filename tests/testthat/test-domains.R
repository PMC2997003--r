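test_that("PROSITE pattern syntax parses into faithful element lists", {
  p <- parsePrositePattern("H-I-G-H.", "PS00178")
  expect_s4_class(p, "PrositePattern")
  expect_length(p@elements, 4L)
  expect_true(all(vapply(p@elements, function(e) e$type == "literal",
                         logical(1))))
  expect_identical(vapply(p@elements, `[[`, "", "residues"),
                   c("H", "I", "G", "H"))

  p <- parsePrositePattern("[AC]-x(2)-D.")
  expect_identical(p@elements[[1]]$type, "set")
  expect_identical(p@elements[[1]]$residues, "AC")
  expect_identical(p@elements[[2]]$type, "any")
  expect_identical(c(p@elements[[2]]$min, p@elements[[2]]$max), c(2L, 2L))
  expect_identical(p@elements[[3]]$residues, "D")

  ## trailing period optional, case-insensitive, ranges, exclusions, anchors
  p <- parsePrositePattern("<a-{pg}-x(1,3)-k>")
  expect_true(p@nTerm); expect_true(p@cTerm)
  expect_identical(p@elements[[2]]$type, "excluded")
  expect_identical(c(p@elements[[3]]$min, p@elements[[3]]$max), c(1L, 3L))
})

test_that("malformed patterns fail with positioned errors", {
  expect_error(parsePrositePattern("[A-C]-x("), "element")
  expect_error(parsePrositePattern("A--C."), "empty element at position 2")
  expect_error(parsePrositePattern("x(3,1)."), "3 > 1")
  expect_error(parsePrositePattern("B."), "non-standard")
  expect_error(parsePrositePattern(""), "non-empty")
})

test_that("pattern matching returns all 1-based starts", {
  expect_identical(matchPrositePattern(parsePrositePattern("H-I-G-H."),
                                       "MAHIGHK"), 3L)
  expect_identical(matchPrositePattern(parsePrositePattern("{P}-G."), "PG"),
                   integer(0))
  expect_identical(matchPrositePattern(parsePrositePattern("x."), "A"), 1L)
  ## overlapping matches are all reported
  expect_identical(matchPrositePattern(parsePrositePattern("A-x-A."),
                                       "AAAAA"), 1:3)
  ## anchors restrict to the termini
  expect_identical(matchPrositePattern(parsePrositePattern("<A-C."), "ACAC"),
                   1L)
  expect_identical(matchPrositePattern(parsePrositePattern("A-C>."), "ACAC"),
                   3L)
  expect_identical(matchPrositePattern(parsePrositePattern("x."), ""),
                   integer(0))
  ## variable-length repeats
  expect_identical(matchPrositePattern(parsePrositePattern("A-x(1,2)-C."),
                                       "ADDC"), 1L)
})

test_that("matcher agrees with a brute-force substring enumerator", {
  set.seed(21)
  ab <- c("A", "C", "G", "H", "I")
  for (rep in 1:60) {
    w <- sample(1:4, 1)
    els <- paste(vapply(seq_len(w), function(k) {
      switch(sample(4, 1),
             sample(ab, 1),
             "x",
             sprintf("[%s]", paste(sample(ab, 2), collapse = "")),
             sprintf("{%s}", sample(ab, 1)))
    }, character(1)), collapse = "-")
    if (runif(1) < 0.2) els <- paste0("<", els)
    if (runif(1) < 0.2) els <- paste0(els, ">")
    p <- parsePrositePattern(paste0(els, "."))
    s <- randSeq(sample(1:12, 1), ab)
    expect_identical(matchPrositePattern(p, s), brutePatternMatch(p, s),
                     info = sprintf("pattern %s on %s", els, s))
  }
})

test_that("domain-hit tables load with set semantics and line-level errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tPS00178", "s1\tPS50889", "s1\tPS00178", "s2\tPS50862"), f)
  ann <- loadDomainHits(f)
  expect_identical(domainHits(ann, "s1"), c("PS00178", "PS50889"))
  expect_identical(domainHits(ann, "s2"), "PS50862")
  expect_identical(domainHits(ann, "absent"), character(0))

  file.create(f)
  expect_length(sequenceIDs(loadDomainHits(f)), 0L)

  writeLines(c("seq_id\taccession", "s1\tPS00178"), f)  # header skipped
  expect_identical(sequenceIDs(loadDomainHits(f)), "s1")

  writeLines(c("s1\tPS00178", "s2\tnot_an_accession"), f)
  expect_error(loadDomainHits(f), "line 2")
})

test_that("annotations round-trip through TSV and merge by union", {
  ann <- domainAnnotation(list(s1 = c("PS00178", "PS50860"), s2 = "PS50889"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDomainHits(ann, f)
  expect_identical(domainHits(loadDomainHits(f)), domainHits(ann))

  other <- domainAnnotation(list(s1 = "PS50862", s3 = "PS50861"))
  merged <- mergeAnnotations(ann, other)
  expect_identical(domainHits(merged, "s1"),
                   c("PS00178", "PS50860", "PS50862"))
  expect_identical(domainHits(merged, "s3"), "PS50861")
})

test_that("binary domain encoding depends only on set membership", {
  ann <- domainAnnotation(list(s1 = "PS00178"))
  v <- encodeDomains(ann, "s1", prositeDomains("stage1"))
  expect_equal(unname(v[1, ]), c(0, 1, 0, 0))

  v <- encodeDomains(ann, "unknown_id", prositeDomains("stage2"))
  expect_equal(unname(v[1, ]), rep(0, 5))

  full <- domainAnnotation(list(s1 = prositeDomains("stage2")))
  v <- encodeDomains(full, "s1", prositeDomains("stage2"))
  expect_equal(unname(v[1, ]), rep(1, 5))

  ## multiplicity and order of hits are irrelevant
  a1 <- domainAnnotation(list(s = c("PS50860", "PS00178", "PS00178")))
  a2 <- domainAnnotation(list(s = c("PS00178", "PS50860")))
  expect_identical(encodeDomains(a1, "s", prositeDomains("stage1")),
                   encodeDomains(a2, "s", prositeDomains("stage1")))

  expect_error(encodeDomains(ann, "s1", character(0)), "non-empty")
  expect_error(encodeDomains(ann, "s1", c("PS00178", "PS00178")),
               "duplicates")
})

test_that("stage-2 domains partition into the class-preferred sets", {
  pref <- classPreferredDomains()
  expect_setequal(pref$class1, c("PS00178", "PS50889"))
  expect_setequal(pref$class2, c("PS50862", "PS50860", "PS50861"))
  expect_length(intersect(pref$class1, pref$class2), 0L)
  expect_setequal(c(pref$class1, pref$class2), prositeDomains("stage2"))
})

test_that("internal scanning finds planted signature motifs", {
  seqs <- c(with_high = paste0(randSeq(30), "HIGH", randSeq(30)),
            plain = "ACDEFACDEFACDEF")
  ann <- scanPatternDomains(seqs)
  expect_true("PS00178" %in% domainHits(ann, "with_high"))
  expect_identical(domainHits(ann, "plain"), character(0))
})
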