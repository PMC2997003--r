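## coerce the various sequence containers to a named character vector
asResidueStrings <- function(x) {
  if (is(x, "LabeledProteinSet")) x <- sequences(x)
  if (is(x, "AAStringSet")) return(stats::setNames(as.character(x), names(x)))
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("expected a LabeledProteinSet, AAStringSet or character vector")
}

#' Amino-acid composition (20 features, percent)
#'
#' The value for residue r is \code{100 * count(r) / length}; features are
#' the 20 standard residues in alphabetical order. Each row sums to 100.
#'
#' @param x sequences: \code{LabeledProteinSet}, \code{AAStringSet} or
#'   named character vector of cleaned residue strings.
#' @return numeric matrix, one row per sequence, 20 named columns.
#' @export
aaComposition <- function(x) {
  seqs <- asResidueStrings(x)
  if (!length(seqs))
    return(matrix(numeric(0), 0, 20, dimnames = list(NULL, aaAlphabet())))
  if (any(!nzchar(seqs))) stop("empty sequence: composition undefined")
  counts <- t(vapply(strsplit(seqs, ""), function(ch)
    tabulate(factor(ch, levels = aaAlphabet()), nbins = 20L),
    integer(20)))
  dimnames(counts) <- list(names(seqs), aaAlphabet())
  100 * counts / nchar(seqs)
}

#' Dipeptide composition (400 features, percent)
#'
#' Counts overlapping length-2 windows: a sequence of length L has L-1
#' windows and the value for dipeptide d is \code{100 * count(d) / (L-1)}.
#' Features are the 400 ordered pairs in grid order (first letter major,
#' alphabetical). Each row sums to 100.
#'
#' @inheritParams aaComposition
#' @return numeric matrix, one row per sequence, 400 named columns.
#' @export
dipeptideComposition <- function(x) {
  seqs <- asResidueStrings(x)
  dn <- dipeptideNames()
  if (!length(seqs))
    return(matrix(numeric(0), 0, 400, dimnames = list(NULL, dn)))
  if (any(nchar(seqs) < 2L))
    stop(sprintf("sequence shorter than 2 residues: %s",
                 paste(names(seqs)[nchar(seqs) < 2L], collapse = ", ")))
  counts <- t(vapply(strsplit(seqs, ""), function(ch) {
    n <- length(ch)
    dip <- paste0(ch[-n], ch[-1])
    tabulate(factor(dip, levels = dn), nbins = 400L)
  }, integer(400)))
  dimnames(counts) <- list(names(seqs), dn)
  100 * counts / (nchar(seqs) - 1L)
}

#' Extract a named sub-vector of features
#'
#' Columns are copied in the requested order; values are not renormalized.
#'
#' @param X feature matrix with column names.
#' @param featureNames ordered character vector of columns to keep.
#' @return feature matrix with \code{length(featureNames)} columns.
#' @export
subsetFeatures <- function(X, featureNames) {
  unknown <- setdiff(featureNames, colnames(X))
  if (length(unknown))
    stop(sprintf("unknown feature name(s): %s",
                 paste(unknown, collapse = ", ")))
  X[, featureNames, drop = FALSE]
}

#' Concatenate feature blocks into a hybrid vector
#'
#' Binds feature matrices column-wise in the given order; the hybrid
#' dimension is the sum of the block dimensions (e.g. 18 selected
#' dipeptides + 4 domain bits = 22; 20 amino acids + 5 domains = 25).
#' Blocks must cover the same sequences and feature names must be disjoint.
#'
#' @param parts non-empty list of feature matrices with identical row names.
#' @return combined feature matrix.
#' @export
assembleHybrid <- function(parts) {
  if (!is.list(parts) || !length(parts)) stop("parts must be a non-empty list")
  rn <- rownames(parts[[1]])
  for (p in parts[-1])
    if (!identical(rownames(p), rn))
      stop("all feature blocks must cover the same sequences in the same order")
  nms <- unlist(lapply(parts, colnames), use.names = FALSE)
  dup <- unique(nms[duplicated(nms)])
  if (length(dup))
    stop(sprintf("duplicated feature name(s) across blocks: %s",
                 paste(dup, collapse = ", ")))
  do.call(cbind, parts)
}

#' Write a feature matrix as TSV
#'
#' First column \code{id}, then one column per feature name.
#'
#' @param X feature matrix with row and column names.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTSV <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
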