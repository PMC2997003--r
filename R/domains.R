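#' Parse a PROSITE pattern string
#'
#' Accepts standard PROSITE pattern syntax: hyphen-separated elements, an
#' optional trailing period, \code{x} wildcards, residue sets
#' \code{[...]}, excluded sets \code{\{...\}}, repeat counts \code{(n)} or
#' ranges \code{(n,m)}, and the terminal anchors \code{<} and \code{>}.
#' Residues are case-insensitive.
#'
#' @param text pattern string, e.g. \code{"H-I-G-H."} or
#'   \code{"[AC]-x(2)-D."}.
#' @param accession accession to record with the pattern.
#' @return a \code{\link{PrositePattern}}.
#' @export
parsePrositePattern <- function(text, accession = "PS00000") {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("pattern text must be a single non-empty string")
  s <- gsub("\\s", "", text)
  s <- sub("\\.$", "", s)
  nTerm <- startsWith(s, "<")
  if (nTerm) s <- substring(s, 2)
  cTerm <- endsWith(s, ">")
  if (cTerm) s <- substring(s, 1, nchar(s) - 1L)
  if (!nzchar(s)) stop("pattern has no elements")
  tokens <- strsplit(s, "-", fixed = TRUE)[[1]]
  elements <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (!nzchar(tok))
      stop(sprintf("empty element at position %d in pattern '%s'", i, text))
    m <- regmatches(tok, regexec(
      "^(x|[A-Za-z]|\\[[A-Za-z]+\\]|\\{[A-Za-z]+\\})(\\(([0-9]+)(,([0-9]+))?\\))?$",
      tok))[[1]]
    if (!length(m))
      stop(sprintf("cannot parse element %d ('%s') of pattern '%s'",
                   i, tok, text))
    core <- m[2]
    minRep <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    maxRep <- if (nzchar(m[6])) as.integer(m[6]) else minRep
    if (maxRep < minRep)
      stop(sprintf("bad repeat range in element %d ('%s'): %d > %d",
                   i, tok, minRep, maxRep))
    el <- if (identical(core, "x")) {
      list(type = "any", residues = "")
    } else if (startsWith(core, "[")) {
      list(type = "set",
           residues = toupper(substr(core, 2, nchar(core) - 1L)))
    } else if (startsWith(core, "{")) {
      list(type = "excluded",
           residues = toupper(substr(core, 2, nchar(core) - 1L)))
    } else {
      list(type = "literal", residues = toupper(core))
    }
    if (el$type != "any") {
      bad <- setdiff(strsplit(el$residues, "")[[1]], aaAlphabet())
      if (length(bad))
        stop(sprintf("non-standard residue(s) %s in element %d of pattern '%s'",
                     paste(bad, collapse = " "), i, text))
    }
    el$min <- minRep
    el$max <- maxRep
    elements[[i]] <- el
  }
  new("PrositePattern", accession = accession, elements = elements,
      nTerm = nTerm, cTerm = cTerm)
}

## translate a parsed pattern into a perl regular expression
patternToRegex <- function(p) {
  body <- vapply(p@elements, function(el) {
    core <- switch(el$type,
      any = ".",
      literal = el$residues,
      set = sprintf("[%s]", el$residues),
      excluded = sprintf("[^%s]", el$residues))
    rep <- if (el$min == 1L && el$max == 1L) ""
           else if (el$min == el$max) sprintf("{%d}", el$min)
           else sprintf("{%d,%d}", el$min, el$max)
    paste0(core, rep)
  }, character(1))
  paste0(body, collapse = "")
}

#' Find all matches of a PROSITE pattern in a sequence
#'
#' Returns every 1-based start position at which the pattern matches
#' (overlapping matches included); anchored patterns only match at the
#' respective terminus. An empty sequence yields an empty result.
#'
#' @param pattern a \code{\link{PrositePattern}}.
#' @param sequence residue string (or \code{AAString}).
#' @return integer vector of 1-based start positions, possibly empty.
#' @export
matchPrositePattern <- function(pattern, sequence) {
  seq <- toupper(as.character(sequence))
  if (!nzchar(seq)) return(integer(0))
  rx <- patternToRegex(pattern)
  if (pattern@cTerm) rx <- paste0(rx, "$")
  rx <- paste0(if (pattern@nTerm) "^" else "", "(?=", rx, ")")
  hits <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Construct a domain annotation
#'
#' @param hits named list mapping sequence id to a character vector of
#'   PROSITE accessions; duplicates within a sequence are collapsed.
#' @return a \code{\link{DomainAnnotation}}.
#' @export
domainAnnotation <- function(hits = list()) {
  hits <- lapply(hits, function(h) sort(unique(as.character(h))))
  hits <- hits[lengths(hits) > 0L]
  new("DomainAnnotation", hits = hits)
}

#' Load per-sequence domain hits from a TSV
#'
#' Expects one hit per row with the sequence id in column 1 and the
#' PROSITE accession in column 2 (a header row is detected and skipped;
#' extra columns are ignored). Duplicate rows collapse to one hit.
#'
#' @param path TSV file.
#' @return a \code{\link{DomainAnnotation}}.
#' @export
loadDomainHits <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(domainAnnotation())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  first <- fields[[1]]
  if (length(first) >= 2L && !grepl("^PS[0-9]{5}$", first[2])) start <- 2L
  if (start > length(lines)) return(domainAnnotation())
  ids <- character(0); accs <- character(0)
  for (i in seq(start, length(lines))) {
    f <- fields[[i]]
    if (length(f) < 2L || !nzchar(f[1]) || !grepl("^PS[0-9]{5}$", f[2]))
      stop(sprintf("malformed domain-hit row at line %d of %s: '%s'",
                   i, path, lines[i]))
    ids <- c(ids, f[1]); accs <- c(accs, f[2])
  }
  domainAnnotation(split(accs, factor(ids, levels = unique(ids))))
}

#' Write a domain annotation as TSV
#'
#' @param ann a \code{DomainAnnotation}.
#' @param path output file.
#' @param header write a header row (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeDomainHits <- function(ann, path, header = TRUE) {
  hits <- domainHits(ann)
  rows <- c(if (header) "seq_id\taccession",
            unlist(lapply(names(hits), function(id)
              paste(id, hits[[id]], sep = "\t")), use.names = FALSE))
  writeLines(rows, path)
  invisible(path)
}

#' Scan sequences for pattern-type domain signatures
#'
#' Runs the built-in PROSITE pattern matcher over a set of sequences and
#' records an accession for every sequence with at least one match. The
#' default signatures are the package's synthetic motif strings
#' (\code{\link{syntheticDomainMotifs}}); real pattern-type signatures can
#' be supplied as parsed \code{PrositePattern}s. Profile-type domains
#' require external scan results (\code{\link{loadDomainHits}}) instead.
#'
#' @param x sequences (any container accepted by \code{\link{aaComposition}}).
#' @param patterns named list of \code{PrositePattern}s, or a named
#'   character vector of exact motif strings (names = accessions).
#' @return a \code{\link{DomainAnnotation}}.
#' @export
scanPatternDomains <- function(x, patterns = syntheticDomainMotifs()) {
  seqs <- asResidueStrings(x)
  if (is.character(patterns))
    patterns <- mapply(function(motif, acc)
      parsePrositePattern(paste(strsplit(motif, "")[[1]], collapse = "-"),
                          accession = acc),
      patterns, names(patterns), SIMPLIFY = FALSE)
  hits <- lapply(seqs, function(s) {
    found <- vapply(patterns, function(p)
      length(matchPrositePattern(p, s)) > 0L, logical(1))
    names(patterns)[found]
  })
  domainAnnotation(hits)
}

#' Merge two domain annotations
#'
#' Union of hit sets per sequence; used to supplement external scan
#' results (which take precedence as the authoritative source) with
#' internally matched pattern-type signatures.
#'
#' @param primary,secondary \code{DomainAnnotation} objects.
#' @return merged \code{DomainAnnotation}.
#' @export
mergeAnnotations <- function(primary, secondary) {
  ids <- union(sequenceIDs(primary), sequenceIDs(secondary))
  domainAnnotation(stats::setNames(lapply(ids, function(id)
    union(domainHits(primary, id), domainHits(secondary, id))), ids))
}

#' Encode domain presence as binary features
#'
#' Bit i of a sequence's vector is 1 iff \code{domainList[i]} is among its
#' hits; sequences absent from the annotation get all-zero vectors. Only
#' set membership matters, never multiplicity or order.
#'
#' @param ann a \code{DomainAnnotation}.
#' @param ids character vector of sequence ids (row order of the result).
#' @param domainList ordered accessions defining the feature columns.
#' @return binary numeric matrix, rows = ids, columns = domainList.
#' @export
encodeDomains <- function(ann, ids, domainList) {
  if (!length(domainList)) stop("domainList must be non-empty")
  if (anyDuplicated(domainList)) stop("domainList must not contain duplicates")
  M <- matrix(0, length(ids), length(domainList),
              dimnames = list(ids, domainList))
  for (i in seq_along(ids))
    M[i, domainList %in% domainHits(ann, ids[i])] <- 1
  M
}
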