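#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' @param x,object an object of one of the package's S4 classes.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("positiveName", function(x) standardGeneric("positiveName"))

#' @rdname accessors
#' @export
setGeneric("negativeName", function(x) standardGeneric("negativeName"))

#' @rdname accessors
#' @export
setGeneric("sequenceIDs", function(x) standardGeneric("sequenceIDs"))

#' @rdname accessors
#' @export
setGeneric("domainHits", function(x, id) standardGeneric("domainHits"))

#' @rdname accessors
#' @export
setGeneric("modelFeatureNames", function(x) standardGeneric("modelFeatureNames"))

#' Signed decision values of a fitted classifier
#'
#' @param object an \code{SVMModel}.
#' @param X numeric feature matrix whose column names equal the model's
#'   feature names, in the same order.
#' @return numeric vector of signed scores; positive values point at the
#'   positive training class.
#' @export
setGeneric("decisionValues", function(object, X) standardGeneric("decisionValues"))

#' Thresholded class predictions of a fitted classifier
#'
#' @param object an \code{SVMModel}.
#' @param X feature matrix as in \code{\link{decisionValues}}.
#' @param threshold decision threshold; a sequence is called positive when
#'   its decision value is \code{>= threshold}. Default 0.
#' @return integer vector of 0/1 labels.
#' @export
setGeneric("predictLabels", function(object, X, threshold = 0) standardGeneric("predictLabels"))

## -- methods --------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("sequences", "LabeledProteinSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("classLabels", "LabeledProteinSet", function(x) {
  stats::setNames(x@labels, names(x@sequences))
})

#' @rdname accessors
#' @export
setMethod("positiveName", "LabeledProteinSet", function(x) x@positiveName)

#' @rdname accessors
#' @export
setMethod("negativeName", "LabeledProteinSet", function(x) x@negativeName)

#' @rdname accessors
#' @export
setMethod("sequenceIDs", "LabeledProteinSet", function(x) names(x@sequences))

#' @rdname accessors
#' @export
setMethod("sequenceIDs", "DomainAnnotation", function(x) names(x@hits))

#' @rdname accessors
#' @export
setMethod("domainHits", "DomainAnnotation", function(x, id) {
  if (missing(id)) return(x@hits)
  hits <- x@hits[[id]]
  if (is.null(hits)) character(0) else hits
})

#' @rdname accessors
#' @export
setMethod("modelFeatureNames", "SVMModel", function(x) x@featureNames)

#' @rdname accessors
#' @export
setMethod("length", "LabeledProteinSet", function(x) length(x@sequences))

#' Subset a labeled set by index, id or logical mask
#'
#' @param x a \code{LabeledProteinSet}.
#' @param i index vector.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "LabeledProteinSet", function(x, i, j, ..., drop = FALSE) {
  new("LabeledProteinSet",
      sequences = x@sequences[i],
      labels = unname(stats::setNames(x@labels, names(x@sequences))[i]),
      positiveName = x@positiveName, negativeName = x@negativeName)
})

#' @rdname accessors
#' @export
setMethod("show", "LabeledProteinSet", function(object) {
  cat(sprintf("LabeledProteinSet: %d sequences (%d %s, %d %s)\n",
              length(object@sequences), sum(object@labels == 1L),
              object@positiveName, sum(object@labels == 0L),
              object@negativeName))
  if (length(object@sequences)) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("  lengths: %d-%d (median %g)\n", min(w), max(w),
                stats::median(w)))
  }
})

#' @rdname accessors
#' @export
setMethod("show", "DomainAnnotation", function(object) {
  accs <- unique(unlist(object@hits, use.names = FALSE))
  cat(sprintf("DomainAnnotation: %d sequences with hits, %d distinct domains\n",
              length(object@hits), length(accs)))
  if (length(accs)) cat(" ", paste(sort(accs), collapse = " "), "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "PrositePattern", function(object) {
  cat(sprintf("PrositePattern %s: %d elements%s%s\n", object@accession,
              length(object@elements),
              if (object@nTerm) " [N-anchored]" else "",
              if (object@cTerm) " [C-anchored]" else ""))
})

#' @rdname accessors
#' @export
setMethod("show", "SVMModel", function(object) {
  cat(sprintf("SVMModel (%s kernel): %d features, %s vs %s\n",
              object@kernel, length(object@featureNames),
              object@positiveName, object@negativeName))
  cat("  params:", paste(names(object@params),
                         unlist(object@params), sep = "=", collapse = " "), "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "TwoStageModel", function(object) {
  cat("TwoStageModel:\n  stage 1: "); show(object@stage1)
  cat("  stage 2: "); show(object@stage2)
  cat(sprintf("  thresholds: %g / %g\n",
              object@thresholds[1], object@thresholds[2]))
})
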