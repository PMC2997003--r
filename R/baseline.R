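#' Local-alignment scoring parameters
#'
#' Smith-Waterman local alignment with affine gap costs
#' (open + k * extend for a gap of length k). Scoring uses either a named
#' substitution matrix (default BLOSUM62) or simple match/mismatch scores.
#' The hit \code{threshold} is the minimum top-hit score for a query to be
#' classified at all; it stands in for BLAST's E-value cut-off and is not
#' equivalent to it.
#'
#' @param substitutionMatrix matrix name (\code{"BLOSUM62"}) or an actual
#'   substitution matrix; ignored when \code{match} is given.
#' @param match,mismatch simple-mode scores (e.g. +2/-1).
#' @param gapOpen,gapExtend non-negative gap costs (default 11/1).
#' @param threshold non-negative minimum hit score (default 0: never
#'   no-hit).
#' @return list of class \code{"AlignmentParams"}.
#' @export
alignmentParams <- function(substitutionMatrix = "BLOSUM62",
                            match = NULL, mismatch = NULL,
                            gapOpen = 11, gapExtend = 1, threshold = 0) {
  if (gapOpen < 0 || gapExtend < 0) stop("gap costs must be non-negative")
  if (threshold < 0) stop("threshold must be non-negative")
  if (!is.null(match)) {
    if (is.null(mismatch)) stop("mismatch score required with match score")
    aa <- aaAlphabet()
    substitutionMatrix <- matrix(as.numeric(mismatch), 20, 20,
                                 dimnames = list(aa, aa))
    diag(substitutionMatrix) <- as.numeric(match)
  } else if (is.character(substitutionMatrix)) {
    name <- substitutionMatrix
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    substitutionMatrix <- get(name, envir = e)
  }
  structure(list(substitutionMatrix = substitutionMatrix,
                 gapOpen = gapOpen, gapExtend = gapExtend,
                 threshold = threshold),
            class = "AlignmentParams")
}

## scores of one query against many subjects (Smith-Waterman, floored at 0)
alignScores <- function(query, subjects, params) {
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects), Biostrings::AAString(query),
    type = "local", substitutionMatrix = params$substitutionMatrix,
    gapOpening = params$gapOpen, gapExtension = params$gapExtend,
    scoreOnly = TRUE)
  pmax(s, 0)
}

#' Smith-Waterman local alignment score
#'
#' Maximal local alignment score with affine gaps; 0 when no
#' positive-scoring alignment exists. Symmetric in its sequence arguments.
#'
#' @param a,b cleaned residue strings.
#' @param params an \code{\link{alignmentParams}} object.
#' @return non-negative numeric score.
#' @export
localAlignScore <- function(a, b, params = alignmentParams()) {
  alignScores(as.character(a), as.character(b), params)
}

#' Classify a query by its top database hit
#'
#' Aligns the query against every database sequence and adopts the label
#' of the highest-scoring one, provided that score reaches the hit
#' threshold; otherwise the query is a no-hit. Ties are broken by database
#' order.
#'
#' @param query a residue string (or \code{AAString}).
#' @param db a \code{LabeledProteinSet} of annotated sequences.
#' @param params an \code{\link{alignmentParams}} object.
#' @return list with \code{label} (0/1 or \code{NA} for no-hit),
#'   \code{score} and \code{hit} (id of the top hit or \code{NA}).
#' @export
topHitClassify <- function(query, db, params = alignmentParams()) {
  if (!length(db)) stop("database must be non-empty")
  s <- alignScores(as.character(query), sequences(db), params)
  best <- which.max(s)
  if (s[best] < params$threshold)
    return(list(label = NA_integer_, score = s[best], hit = NA_character_))
  list(label = unname(classLabels(db)[best]), score = s[best],
       hit = sequenceIDs(db)[best])
}

#' Cross-validated similarity-search baseline
#'
#' For each fold, the other folds form the annotated database and every
#' held-out sequence is classified by its top local-alignment hit. No-hit
#' accounting follows the published convention: a positive without any
#' hit counts as a false negative and a negative without any hit as a
#' false positive (\code{accounting = "as-published"});
#' \code{"corrected"} counts no-hit negatives as true negatives instead.
#'
#' @param ds a \code{LabeledProteinSet}.
#' @param folds fold assignment from \code{\link{makeFolds}}.
#' @param params an \code{\link{alignmentParams}} object.
#' @param accounting no-hit accounting rule.
#' @return list with \code{perFold}, \code{mean}, \code{pooled},
#'   \code{pooledCounts} and the per-sequence \code{calls} data.frame.
#' @export
cvSimilarityEval <- function(ds, folds, params = alignmentParams(),
                             accounting = c("as-published", "corrected")) {
  accounting <- match.arg(accounting)
  ids <- sequenceIDs(ds)
  if (!all(ids %in% names(folds))) stop("folds must cover every sequence")
  f <- folds[ids]
  y <- unname(classLabels(ds))
  k <- max(f)
  perFold <- vector("list", k)
  pooled <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  calls <- data.frame(id = ids, label = y, predicted = NA_integer_,
                      score = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    test <- which(f == i)
    db <- ds[which(f != i)]
    counts <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
    for (j in test) {
      hit <- topHitClassify(sequences(ds)[[j]], db, params)
      calls$predicted[j] <- hit$label
      calls$score[j] <- hit$score
      counts <- counts + if (is.na(hit$label)) {
        if (y[j] == 1L) c(TP = 0L, TN = 0L, FP = 0L, FN = 1L)
        else if (accounting == "as-published")
          c(TP = 0L, TN = 0L, FP = 1L, FN = 0L)
        else c(TP = 0L, TN = 1L, FP = 0L, FN = 0L)
      } else confusionCounts(y[j], hit$label)
    }
    pooled <- pooled + counts
    perFold[[i]] <- c(fold = i, counts, classMetrics(counts))
  }
  perFold <- as.data.frame(do.call(rbind, perFold))
  list(perFold = perFold,
       mean = colMeans(perFold[, c("sensitivity", "specificity",
                                   "accuracy", "mcc")]),
       pooled = classMetrics(pooled), pooledCounts = pooled,
       calls = calls)
}

#' Read 12-column tabular alignment hits
#'
#' Reader for the standard tabular output of external search tools
#' (query, subject, identity, length, mismatches, gap opens, qstart,
#' qend, sstart, send, evalue, bitscore), so externally computed hits can
#' substitute for the internal aligner.
#'
#' @param path tabular hits file.
#' @return data.frame with columns query, subject and bitscore.
#' @export
readTabularHits <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12L)
    stop("expected 12-column tabular hit format")
  data.frame(query = as.character(tab[[1]]),
             subject = as.character(tab[[2]]),
             bitscore = as.numeric(tab[[12]]),
             stringsAsFactors = FALSE)
}
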