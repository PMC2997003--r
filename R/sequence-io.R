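#' Clean a raw residue string
#'
#' Case-folds to upper case and handles characters outside the 20-letter
#' amino-acid alphabet. Under \code{"strict"} any non-standard character is
#' an error; under \code{"drop_nonstandard"} (the default policy of the
#' readers) offending characters (B, Z, X, U, O, J, gaps, ...) are removed
#' with a warning, so composition denominators use the cleaned length.
#' Cleaning is idempotent.
#'
#' @param raw non-empty character string of residues.
#' @param policy \code{"strict"} or \code{"drop_nonstandard"}.
#' @param id optional sequence id used in messages.
#' @return cleaned residue string.
#' @export
cleanSequence <- function(raw, policy = c("drop_nonstandard", "strict"),
                          id = NULL) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("raw must be a single non-empty string")
  up <- toupper(raw)
  chars <- strsplit(up, "")[[1]]
  bad <- which(!chars %in% aaAlphabet())
  who <- if (is.null(id)) "sequence" else sprintf("sequence '%s'", id)
  if (length(bad)) {
    if (policy == "strict")
      stop(sprintf("%s contains non-standard characters: %s", who,
                   paste(sprintf("'%s' at %d", chars[bad], bad),
                         collapse = ", ")))
    warning(sprintf("%s: dropped %d non-standard character(s): %s", who,
                    length(bad),
                    paste(unique(chars[bad]), collapse = " ")))
    chars <- chars[-bad]
    if (!length(chars))
      stop(sprintf("%s is empty after removing non-standard characters", who))
    return(paste(chars, collapse = ""))
  }
  up
}

#' Read protein sequences from a FASTA file
#'
#' One record per FASTA entry, in file order; the header token up to the
#' first whitespace becomes the id. Sequences are validated (and, under the
#' default policy, cleaned) against the 20-letter alphabet.
#'
#' @param path FASTA file.
#' @param policy residue-cleaning policy, see \code{\link{cleanSequence}}.
#' @return named \code{AAStringSet}.
#' @export
readProteinFasta <- function(path, policy = c("drop_nonstandard", "strict")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e)
                    stop(sprintf("malformed FASTA in %s: %s", path,
                                 conditionMessage(e))))
  if (!length(set)) return(Biostrings::AAStringSet())
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop(sprintf("record %d in %s has an empty header",
                 which(!nzchar(ids))[1], path))
  if (anyDuplicated(ids))
    stop(sprintf("duplicated ids in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  empty <- which(Biostrings::width(set) == 0L)
  if (length(empty))
    stop(sprintf("record '%s' in %s has an empty sequence",
                 ids[empty[1]], path))
  res <- vapply(seq_along(set), function(i)
    cleanSequence(as.character(set[[i]]), policy = policy, id = ids[i]),
    character(1))
  Biostrings::AAStringSet(stats::setNames(res, ids))
}

#' Write protein sequences to FASTA
#'
#' @param seqs named \code{AAStringSet} or named character vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeProteinFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Construct a labeled protein set
#'
#' @param sequences named \code{AAStringSet} or named character vector.
#' @param labels integer/numeric vector of 0/1, parallel to sequences.
#' @param positiveName,negativeName class names.
#' @return a \code{\link{LabeledProteinSet}}.
#' @export
labeledProteinSet <- function(sequences, labels, positiveName = "positive",
                              negativeName = "negative") {
  if (is.character(sequences)) sequences <- Biostrings::AAStringSet(sequences)
  new("LabeledProteinSet", sequences = sequences,
      labels = as.integer(labels),
      positiveName = positiveName, negativeName = negativeName)
}

#' Load a labeled two-class dataset from a FASTA pair
#'
#' Records from \code{posPath} are labeled 1 and records from
#' \code{negPath} 0. An id present in both files is an error, as is an
#' empty file.
#'
#' @param posPath,negPath FASTA files of the positive and negative class.
#' @param positiveName,negativeName class names stored with the labels.
#' @param policy residue-cleaning policy.
#' @return a \code{\link{LabeledProteinSet}}.
#' @export
loadLabeledDataset <- function(posPath, negPath,
                               positiveName = "aaRS",
                               negativeName = "non-aaRS",
                               policy = c("drop_nonstandard", "strict")) {
  policy <- match.arg(policy)
  pos <- readProteinFasta(posPath, policy)
  neg <- readProteinFasta(negPath, policy)
  if (!length(pos)) stop(sprintf("positive file %s has no records", posPath))
  if (!length(neg)) stop(sprintf("negative file %s has no records", negPath))
  shared <- intersect(names(pos), names(neg))
  if (length(shared))
    stop(sprintf("ids present in both files: %s",
                 paste(shared, collapse = ", ")))
  labeledProteinSet(c(pos, neg),
                    c(rep(1L, length(pos)), rep(0L, length(neg))),
                    positiveName, negativeName)
}

#' Write a labeled dataset as a FASTA pair
#'
#' @param ds a \code{LabeledProteinSet}.
#' @param posPath,negPath output FASTA files.
#' @return invisibly, c(posPath, negPath).
#' @export
writeLabeledDataset <- function(ds, posPath, negPath) {
  lab <- classLabels(ds)
  writeProteinFasta(sequences(ds)[lab == 1L], posPath)
  writeProteinFasta(sequences(ds)[lab == 0L], negPath)
  invisible(c(posPath, negPath))
}

#' Read a two-column id/label table as labels
#'
#' Alternative labeled-set input: a TSV with columns \code{id} and
#' \code{label} (1/0 or the class names), paired with a single FASTA.
#'
#' @param fastaPath FASTA of all sequences.
#' @param labelPath TSV with columns id, label (header optional).
#' @param positiveName,negativeName class names; rows whose label equals
#'   \code{positiveName} (or 1) are positives.
#' @param policy residue-cleaning policy.
#' @return a \code{\link{LabeledProteinSet}}.
#' @export
loadLabeledTSV <- function(fastaPath, labelPath,
                           positiveName = "aaRS", negativeName = "non-aaRS",
                           policy = c("drop_nonstandard", "strict")) {
  policy <- match.arg(policy)
  seqs <- readProteinFasta(fastaPath, policy)
  tab <- utils::read.delim(labelPath, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label table must have two columns: id, label")
  if (identical(tolower(tab[1, 1]), "id")) tab <- tab[-1, , drop = FALSE]
  ids <- as.character(tab[[1]])
  raw <- as.character(tab[[2]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicated ids in label table: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  missing <- setdiff(ids, names(seqs))
  if (length(missing))
    stop(sprintf("labeled ids missing from FASTA: %s",
                 paste(missing, collapse = ", ")))
  lab <- ifelse(raw %in% c("1", positiveName), 1L,
                ifelse(raw %in% c("0", negativeName), 0L, NA_integer_))
  if (anyNA(lab))
    stop(sprintf("unrecognized labels: %s",
                 paste(unique(raw[is.na(lab)]), collapse = ", ")))
  labeledProteinSet(seqs[ids], lab, positiveName, negativeName)
}
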