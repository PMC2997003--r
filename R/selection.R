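#' Rank features by recursive linear-SVM weight elimination
#'
#' Iteratively trains a linear soft-margin SVM, scores each surviving
#' feature by its squared primal weight, eliminates the lowest-scoring
#' batch, and repeats until no features remain. The final rank is the
#' reverse elimination order (rank 1 = last survivor). With 50 or fewer
#' surviving features one feature is eliminated per round; above that, a
#' fraction of the survivors is dropped per round to keep 400-feature runs
#' fast. Score ties are broken by feature name (lexicographically earlier
#' names rank better). Deterministic for fixed inputs and seed.
#'
#' @param X feature matrix with named columns.
#' @param y binary 0/1 labels.
#' @param batchFraction fraction of survivors eliminated per round when
#'   more than 50 remain (default 0.1).
#' @param cost linear-SVM regularization weight (default 1).
#' @param seed integer seed recorded for reproducibility.
#' @return data.frame with columns \code{name}, \code{rank} (1..p) and
#'   \code{score} (squared weight at the feature's elimination round).
#' @export
rankFeatures <- function(X, y, batchFraction = 0.1, cost = 1, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column (feature) names")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("ranking requires both classes")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  if (batchFraction <= 0 || batchFraction >= 1)
    stop("batchFraction must be in (0, 1)")
  surviving <- colnames(X)
  elimName <- character(0)
  elimScore <- numeric(0)
  while (length(surviving)) {
    if (length(surviving) == 1L) {
      ## a lone feature needs no fit to be ranked first
      elimName <- c(elimName, surviving)
      elimScore <- c(elimScore, NA_real_)
      break
    }
    m <- trainSVM(X[, surviving, drop = FALSE], y, kernel = "linear",
                  cost = cost, seed = seed)
    score <- linearWeights(m)^2
    nElim <- if (length(surviving) <= 50L) 1L
             else min(ceiling(batchFraction * length(surviving)),
                      length(surviving) - 1L)
    ## lowest score first; ties: lexicographically later name drops first
    ord <- order(score, -xtfrm(names(score)))
    drop <- names(score)[ord[seq_len(nElim)]]
    elimName <- c(elimName, drop)
    elimScore <- c(elimScore, unname(score[drop]))
    surviving <- setdiff(surviving, drop)
  }
  data.frame(name = rev(elimName),
             rank = seq_along(elimName),
             score = rev(elimScore),
             stringsAsFactors = FALSE)
}

#' Best-ranked feature names
#'
#' @param ranking a data.frame from \code{\link{rankFeatures}}.
#' @param k number of features to keep (1..nrow(ranking)).
#' @return character vector of the k best-ranked names, in rank order.
#' @export
selectTopK <- function(ranking, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > nrow(ranking))
    stop(sprintf("k must be in 1..%d", nrow(ranking)))
  ranking$name[order(ranking$rank)][seq_len(as.integer(k))]
}

#' Write a feature ranking as TSV
#'
#' @param ranking a data.frame from \code{\link{rankFeatures}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRanking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
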