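#' Feature/classifier pipeline configuration
#'
#' Describes one of the prediction approaches: which feature blocks to
#' build, which stage's default dipeptide and domain lists to use, and the
#' SVM settings.
#'
#' Feature modes: \code{"aac"} (20 amino-acid percentages), \code{"dpc"}
#' (400 dipeptide percentages), \code{"dpc-selected"} (the stage's
#' selected dipeptides), \code{"domain"} (binary domain bits only),
#' \code{"hybrid1"} (aac + domains: 24 or 25 dimensions),
#' \code{"hybrid2"} (selected dipeptides + domains: 22 or 19), and
#' \code{"dpc-hybrid"} (all 400 dipeptides + domains: 404 or 405).
#'
#' @param features feature mode, see Details.
#' @param stage \code{"stage1"} (aaRS vs non-aaRS) or \code{"stage2"}
#'   (class-1 vs class-2); sets the default dipeptide/domain lists and
#'   class names.
#' @param dipeptides override of the selected-dipeptide list.
#' @param domains override of the domain accession list.
#' @param kernel,cost,gamma,threshold SVM settings (defaults: RBF kernel,
#'   C = 1, gamma = 1/dimension, decision threshold 0).
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(features = c("hybrid2", "aac", "dpc",
                                        "dpc-selected", "domain",
                                        "hybrid1", "dpc-hybrid"),
                           stage = c("stage1", "stage2"),
                           dipeptides = NULL, domains = NULL,
                           kernel = "radial", cost = 1, gamma = NULL,
                           threshold = 0) {
  features <- match.arg(features)
  stage <- match.arg(stage)
  if (is.null(dipeptides)) dipeptides <- selectedDipeptides(stage)
  if (is.null(domains)) domains <- prositeDomains(stage)
  structure(list(features = features, stage = stage,
                 dipeptides = dipeptides, domains = domains,
                 kernel = kernel, cost = cost, gamma = gamma,
                 threshold = threshold),
            class = "PipelineConfig")
}

needsDomains <- function(config) {
  config$features %in% c("domain", "hybrid1", "hybrid2", "dpc-hybrid")
}

#' Build the feature matrix of a pipeline
#'
#' @param x sequences (\code{LabeledProteinSet}, \code{AAStringSet} or
#'   named character vector).
#' @param config a \code{\link{pipelineConfig}}.
#' @param ann \code{DomainAnnotation}; required by domain and hybrid
#'   modes.
#' @return numeric feature matrix, one row per sequence.
#' @export
buildFeatureMatrix <- function(x, config, ann = NULL) {
  seqs <- asResidueStrings(x)
  ids <- names(seqs)
  if (needsDomains(config) && is.null(ann))
    stop(sprintf("feature mode '%s' requires a domain annotation",
                 config$features))
  switch(config$features,
    "aac" = aaComposition(seqs),
    "dpc" = dipeptideComposition(seqs),
    "dpc-selected" = subsetFeatures(dipeptideComposition(seqs),
                                    config$dipeptides),
    "domain" = encodeDomains(ann, ids, config$domains),
    "hybrid1" = assembleHybrid(list(
      aaComposition(seqs), encodeDomains(ann, ids, config$domains))),
    "hybrid2" = assembleHybrid(list(
      subsetFeatures(dipeptideComposition(seqs), config$dipeptides),
      encodeDomains(ann, ids, config$domains))),
    "dpc-hybrid" = assembleHybrid(list(
      dipeptideComposition(seqs),
      encodeDomains(ann, ids, config$domains))))
}

#' Train a stage model from a labeled set and a pipeline config
#'
#' @param ds a \code{LabeledProteinSet}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param ann \code{DomainAnnotation} (for domain/hybrid modes).
#' @param seed integer seed.
#' @return an \code{\link{SVMModel}} whose metadata records the pipeline,
#'   so that \code{\link{twoStagePredict}} can rebuild matching features.
#' @export
trainStageModel <- function(ds, config, ann = NULL, seed = 1L) {
  X <- buildFeatureMatrix(ds, config, ann)
  trainSVM(X, classLabels(ds), kernel = config$kernel, cost = config$cost,
           gamma = config$gamma, seed = seed,
           positiveName = positiveName(ds), negativeName = negativeName(ds),
           featureConfig = unclass(config))
}

#' Bundle two stage models into a cascade
#'
#' @param stage1,stage2 \code{SVMModel}s trained via
#'   \code{\link{trainStageModel}}.
#' @param thresholds numeric length-2 decision thresholds.
#' @return a \code{\link{TwoStageModel}}.
#' @export
twoStageModel <- function(stage1, stage2, thresholds = c(0, 0)) {
  new("TwoStageModel", stage1 = stage1, stage2 = stage2,
      thresholds = as.numeric(thresholds))
}

modelConfig <- function(model) {
  cfg <- model@metadata$featureConfig
  if (is.null(cfg) || !length(cfg))
    stop("model carries no feature pipeline; train it with trainStageModel()")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Two-stage aaRS prediction
#'
#' Stage 1 scores every query as aaRS vs non-aaRS; only stage-1 positives
#' are passed to stage 2, which assigns class-1 (the stage-2 positive
#' label) versus class-2. Queries rejected at stage 1 get \code{NA} stage-2
#' scores and the stage-1 negative label as their final call.
#'
#' @param x query sequences (any container accepted by
#'   \code{\link{buildFeatureMatrix}}).
#' @param model a \code{\link{TwoStageModel}}.
#' @param ann \code{DomainAnnotation} for the queries; when \code{NULL}
#'   and a hybrid/domain mode needs one, the built-in pattern matcher is
#'   used (\code{\link{scanPatternDomains}}).
#' @return data.frame: id, stage1_score, stage1_label, stage2_score,
#'   final_label.
#' @export
twoStagePredict <- function(x, model, ann = NULL) {
  stopifnot(is(model, "TwoStageModel"))
  seqs <- asResidueStrings(x)
  cfg1 <- modelConfig(model@stage1)
  cfg2 <- modelConfig(model@stage2)
  if (is.null(ann) && (needsDomains(cfg1) || needsDomains(cfg2)))
    ann <- scanPatternDomains(seqs)
  th <- model@thresholds
  dv1 <- decisionValues(model@stage1, buildFeatureMatrix(seqs, cfg1, ann))
  isPos <- dv1 >= th[1]
  dv2 <- rep(NA_real_, length(seqs))
  final <- rep(model@stage1@negativeName, length(seqs))
  if (any(isPos)) {
    dv2[isPos] <- decisionValues(
      model@stage2, buildFeatureMatrix(seqs[isPos], cfg2, ann))
    final[isPos] <- ifelse(dv2[isPos] >= th[2],
                           model@stage2@positiveName,
                           model@stage2@negativeName)
  }
  data.frame(id = names(seqs),
             stage1_score = unname(dv1),
             stage1_label = ifelse(isPos, model@stage1@positiveName,
                                   model@stage1@negativeName),
             stage2_score = dv2,
             final_label = final,
             stringsAsFactors = FALSE, row.names = NULL)
}
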