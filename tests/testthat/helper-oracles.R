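## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## random residue string
randSeq <- function(len, alphabet = aaAlphabet()) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## dipeptide counts by direct substring enumeration
bruteDipeptideCounts <- function(seq) {
  n <- nchar(seq)
  if (n < 2) return(table(character(0)))
  table(vapply(seq_len(n - 1), function(i) substr(seq, i, i + 1),
               character(1)))
}

## Smith-Waterman with affine gaps (Gotoh), gap of length k costs
## open + k * ext; score floored at 0
swOracle <- function(a, b, submat, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (horizontal)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext)
      s <- submat[A[i], B[j]]
      M[i + 1, j + 1] <- max(0,
                             max(M[i, j], Ix[i, j], Iy[i, j]) + s)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

simpleSubMat <- function(match = 2, mismatch = -1) {
  aa <- aaAlphabet()
  m <- matrix(mismatch, 20, 20, dimnames = list(aa, aa))
  diag(m) <- match
  m
}

## all starts where a fixed-length pattern (no repeat ranges) matches,
## by direct per-position comparison
brutePatternMatch <- function(pat, seq) {
  els <- pat@elements
  stopifnot(all(vapply(els, function(e) e$min == 1L && e$max == 1L,
                       logical(1))))
  chars <- strsplit(toupper(seq), "")[[1]]
  w <- length(els)
  if (length(chars) < w) return(integer(0))
  starts <- if (pat@nTerm) 1L else seq_len(length(chars) - w + 1L)
  hits <- starts[vapply(starts, function(p) {
    if (pat@cTerm && p + w - 1L != length(chars)) return(FALSE)
    all(vapply(seq_len(w), function(k) {
      el <- els[[k]]; ch <- chars[p + k - 1L]
      switch(el$type,
             any = TRUE,
             literal = ch == el$residues,
             set = grepl(ch, el$residues, fixed = TRUE),
             excluded = !grepl(ch, el$residues, fixed = TRUE))
    }, logical(1)))
  }, logical(1))]
  as.integer(hits)
}

## AUC as the normalized Mann-Whitney U statistic, by pairwise comparison
mannWhitneyAUC <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

## confusion recount by explicit looping
bruteConfusion <- function(y, p) {
  out <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (i in seq_along(y)) {
    key <- if (y[i] == 1 && p[i] == 1) "TP"
      else if (y[i] == 0 && p[i] == 0) "TN"
      else if (y[i] == 0 && p[i] == 1) "FP"
      else "FN"
    out[key] <- out[key] + 1L
  }
  out
}

## the 21 published threshold-sweep rows of the hybrid stage-1 model on
## the 44-positive / 450-negative independent set
independentSetSweep <- function() {
  txt <- "threshold sensitivity specificity accuracy mcc
-1.0 100.00 43.11 48.18 0.25
-0.9 97.73 63.56 66.60 0.35
-0.8 81.82 82.44 82.39 0.43
-0.7 72.73 92.22 90.49 0.54
-0.6 63.64 97.11 94.13 0.63
-0.5 54.55 99.56 95.55 0.69
-0.4 52.27 100.00 95.75 0.71
-0.3 52.27 100.00 95.75 0.71
-0.2 52.27 100.00 95.75 0.71
-0.1 52.27 100.00 95.75 0.71
0.0 52.27 100.00 95.75 0.71
0.1 52.27 100.00 95.75 0.71
0.2 52.27 100.00 95.75 0.71
0.3 52.27 100.00 95.75 0.71
0.4 52.27 100.00 95.75 0.71
0.5 47.73 100.00 95.34 0.67
0.6 43.18 100.00 94.94 0.64
0.7 36.36 100.00 94.33 0.59
0.8 22.73 100.00 93.12 0.46
0.9 18.18 100.00 92.71 0.41
1.0 11.36 100.00 92.11 0.32"
  read.table(text = txt, header = TRUE)
}

## back-solve confusion counts from printed sensitivity/specificity at
## fixed class sizes
backSolveCounts <- function(sens, spec, nPos, nNeg) {
  tp <- round(sens / 100 * nPos)
  tn <- round(spec / 100 * nNeg)
  c(TP = tp, TN = tn, FP = nNeg - tn, FN = nPos - tp)
}

## small FASTA writer independent of the package
writeFastaRaw <- function(seqs, path, wrap = NULL) {
  lines <- unlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    body <- if (is.null(wrap)) s
            else substring(s, seq(1, nchar(s), wrap),
                           pmin(seq(1, nchar(s), wrap) + wrap - 1, nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
}
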