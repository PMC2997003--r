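#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

#' Labeled protein sequence set
#'
#' Container pairing an \code{AAStringSet} of validated protein sequences
#' with binary class labels (1 = positive class, 0 = negative class) and
#' human-readable class names.
#'
#' @slot sequences \code{AAStringSet}, one entry per protein, unique names.
#' @slot labels integer vector of 0/1, parallel to \code{sequences}.
#' @slot positiveName,negativeName single strings naming the two classes
#'   (e.g. \code{"aaRS"} / \code{"non-aaRS"}).
#'
#' @exportClass LabeledProteinSet
setClass("LabeledProteinSet",
  representation(
    sequences = "AAStringSet",
    labels = "integer",
    positiveName = "character",
    negativeName = "character"
  )
)

setValidity("LabeledProteinSet", function(object) {
  ids <- names(object@sequences)
  if (length(object@labels) != length(object@sequences))
    return("labels and sequences must have equal length")
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    return("every sequence must have a non-empty id")
  if (anyDuplicated(ids))
    return(sprintf("duplicated sequence ids: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@sequences) && any(Biostrings::width(object@sequences) < 1L))
    return("empty sequences are not allowed")
  if (any(!object@labels %in% c(0L, 1L)))
    return("labels must be 0 or 1")
  if (length(object@positiveName) != 1L || length(object@negativeName) != 1L)
    return("positiveName and negativeName must be single strings")
  if (identical(object@positiveName, object@negativeName))
    return("positiveName and negativeName must differ")
  TRUE
})

#' Per-sequence PROSITE domain hits
#'
#' Maps sequence ids to the set of PROSITE accessions (\code{PSnnnnn})
#' observed in that sequence, as reported by an external profile/pattern
#' scanner or by the built-in pattern matcher.
#'
#' @slot hits named list; each element a character vector of accessions.
#'
#' @exportClass DomainAnnotation
setClass("DomainAnnotation", representation(hits = "list"))

setValidity("DomainAnnotation", function(object) {
  h <- object@hits
  if (length(h)) {
    if (is.null(names(h)) || any(!nzchar(names(h))))
      return("hits must be named by sequence id")
    if (anyDuplicated(names(h)))
      return("duplicated sequence ids in hits")
    accs <- unlist(h, use.names = FALSE)
    bad <- accs[!grepl("^PS[0-9]{5}$", accs)]
    if (length(bad))
      return(sprintf("malformed accessions (expected PS + 5 digits): %s",
                     paste(unique(bad), collapse = ", ")))
    if (any(vapply(h, anyDuplicated, 0L) > 0L))
      return("hit sets must not contain duplicates")
  }
  TRUE
})

#' Parsed PROSITE pattern
#'
#' A PROSITE sequence pattern (hyphen-separated elements, optional repeat
#' counts, optional \code{<} / \code{>} anchors) in structured form. Each
#' element is a list with fields \code{type} (one of \code{"literal"},
#' \code{"any"}, \code{"set"}, \code{"excluded"}), \code{residues}, and the
#' repeat range \code{min}/\code{max}.
#'
#' @slot accession PROSITE accession the pattern belongs to.
#' @slot elements ordered list of pattern elements.
#' @slot nTerm,cTerm logical anchor flags.
#'
#' @exportClass PrositePattern
setClass("PrositePattern",
  representation(
    accession = "character",
    elements = "list",
    nTerm = "logical",
    cTerm = "logical"
  )
)

setValidity("PrositePattern", function(object) {
  if (!length(object@elements)) return("pattern must have at least one element")
  for (el in object@elements) {
    if (!el$type %in% c("literal", "any", "set", "excluded"))
      return(sprintf("unknown element type '%s'", el$type))
    if (el$type != "any" && any(!strsplit(el$residues, "")[[1]] %in% aaAlphabet()))
      return(sprintf("non-standard residue in element '%s'", el$residues))
    if (el$min < 0L || el$max < el$min)
      return("repeat range must satisfy 0 <= min <= max")
  }
  TRUE
})

#' Fitted support vector machine classifier
#'
#' Wraps a fitted soft-margin SVM together with everything scoring
#' requires: the exact ordered feature names, kernel and hyperparameters,
#' class names, a decision-value orientation flag (so positive scores
#' always mean the positive class), and training metadata.
#'
#' @slot fit the underlying \pkg{e1071} model object.
#' @slot kernel \code{"linear"}, \code{"polynomial"} or \code{"radial"}.
#' @slot featureNames ordered character vector; scored matrices must match.
#' @slot params list of hyperparameters (cost, gamma or degree).
#' @slot positiveName,negativeName class names.
#' @slot flipSign logical; TRUE when raw libsvm decision values point at
#'   the negative class and must be negated.
#' @slot metadata list (seed, date, training-data hash, featureConfig).
#'
#' @exportClass SVMModel
setClass("SVMModel",
  representation(
    fit = "ANY",
    kernel = "character",
    featureNames = "character",
    params = "list",
    positiveName = "character",
    negativeName = "character",
    flipSign = "logical",
    metadata = "list"
  )
)

setValidity("SVMModel", function(object) {
  if (!object@kernel %in% c("linear", "polynomial", "radial"))
    return("kernel must be linear, polynomial or radial")
  if (!length(object@featureNames)) return("featureNames must be non-empty")
  if (anyDuplicated(object@featureNames)) return("featureNames must be unique")
  TRUE
})

#' Two-stage aaRS predictor
#'
#' Cascade of two fitted models: stage 1 discriminates aaRS from non-aaRS;
#' stage 2 runs only on stage-1 positives and assigns class-1 (positive)
#' versus class-2 (negative). Each stage carries its own feature pipeline
#' in the model metadata.
#'
#' @slot stage1,stage2 \code{SVMModel} objects.
#' @slot thresholds numeric length-2 decision thresholds (stage 1, stage 2).
#'
#' @exportClass TwoStageModel
setClass("TwoStageModel",
  representation(
    stage1 = "SVMModel",
    stage2 = "SVMModel",
    thresholds = "numeric"
  )
)

setValidity("TwoStageModel", function(object) {
  if (length(object@thresholds) != 2L)
    return("thresholds must be length 2 (stage 1, stage 2)")
  TRUE
})
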