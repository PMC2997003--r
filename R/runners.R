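#' Write a reproducibility manifest
#'
#' Flat key=value text recording the run configuration, seed, package
#' version and md5 hashes of every input file.
#'
#' @param path output file.
#' @param config named list of settings.
#' @param inputs character vector of input file paths.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(path, config, inputs = character(0)) {
  lines <- c(sprintf("package=aaRSpred %s",
                     as.character(utils::packageVersion("aaRSpred"))),
             sprintf("date=%s", format(Sys.time())),
             vapply(names(config), function(k)
               sprintf("%s=%s", k,
                       paste(format(config[[k]]), collapse = ",")),
               character(1)))
  inputs <- inputs[file.exists(inputs)]
  if (length(inputs))
    lines <- c(lines, sprintf("input.%s=%s", basename(inputs),
                              unname(tools::md5sum(inputs))))
  writeLines(lines, path)
  invisible(path)
}

#' Cross-validate all prediction approaches on one dataset
#'
#' Runs stratified k-fold cross-validation for each requested feature
#' mode, reusing one fold split across approaches so comparisons are
#' paired, and writes one report (per-fold rows plus fold-mean and
#' pooled-count summaries) per approach. Domain-dependent modes fail
#' before any training when no domain source is available.
#'
#' @param posPath,negPath FASTA files of the two classes.
#' @param hitsPath optional domain-hit TSV; when absent and a mode needs
#'   domains, \code{scanInternal = TRUE} falls back to the built-in
#'   pattern matcher.
#' @param stage \code{"stage1"} or \code{"stage2"} (default lists/names).
#' @param modes feature modes to run (see \code{\link{pipelineConfig}}).
#' @param k,seed folds and split seed.
#' @param kernel,cost,gamma SVM settings shared by all modes.
#' @param outDir output directory for TSV reports and the manifest;
#'   \code{NULL} writes nothing.
#' @param scanInternal allow the internal pattern matcher as the domain
#'   source when \code{hitsPath} is missing.
#' @return named list of \code{\link{crossValidate}} reports, invisibly
#'   when \code{outDir} is set.
#' @export
runCrossval <- function(posPath, negPath, hitsPath = NULL,
                        stage = c("stage1", "stage2"),
                        modes = c("domain", "aac", "dpc", "dpc-selected",
                                  "hybrid1", "hybrid2"),
                        k = 5, seed = 1L, kernel = "radial", cost = 1,
                        gamma = NULL, outDir = NULL, scanInternal = FALSE) {
  stage <- match.arg(stage)
  posNeg <- if (stage == "stage1") c("aaRS", "non-aaRS")
            else c("class-1", "class-2")
  ds <- loadLabeledDataset(posPath, negPath, posNeg[1], posNeg[2])
  configs <- lapply(modes, function(m)
    pipelineConfig(m, stage, kernel = kernel, cost = cost, gamma = gamma))
  names(configs) <- modes
  ann <- NULL
  if (any(vapply(configs, needsDomains, logical(1)))) {
    if (!is.null(hitsPath)) ann <- loadDomainHits(hitsPath)
    else if (scanInternal) ann <- scanPatternDomains(ds)
    else stop("domain/hybrid modes need a hit table (or scanInternal=TRUE)")
  }
  folds <- makeFolds(ds, k, seed)
  reports <- lapply(configs, function(cfg)
    crossValidate(ds, cfg, ann, folds = folds, seed = seed))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (m in modes) {
      r <- reports[[m]]
      summary <- rbind(
        data.frame(set = sprintf("fold%d", r$perFold$fold),
                   presentMetrics(r$perFold[, c("sensitivity",
                                                "specificity", "accuracy",
                                                "mcc")])),
        data.frame(set = "mean", t(presentMetrics(r$mean))),
        data.frame(set = "pooled", t(presentMetrics(r$pooled))))
      utils::write.table(summary, file.path(outDir,
                                            sprintf("crossval_%s.tsv", m)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeManifest(file.path(outDir, "manifest.txt"),
                  list(command = "crossval", stage = stage,
                       modes = paste(modes, collapse = ","), k = k,
                       seed = seed, kernel = kernel, cost = cost,
                       gamma = if (is.null(gamma)) "1/dim" else gamma),
                  c(posPath, negPath, hitsPath))
    return(invisible(reports))
  }
  reports
}

#' Batch two-stage prediction to TSV
#'
#' @param model a \code{\link{TwoStageModel}} or path to one saved with
#'   \code{\link{saveModel}}.
#' @param queryPath FASTA of query sequences.
#' @param hitsPath optional domain-hit TSV for the queries; when absent
#'   the built-in pattern matcher supplies pattern-type hits.
#' @param out output TSV path; \code{NULL} returns the data.frame only.
#' @return the predictions data.frame (id, stage1_score, stage1_label,
#'   stage2_score, final_label), invisibly when written.
#' @export
runPredict <- function(model, queryPath, hitsPath = NULL, out = NULL) {
  if (is.character(model)) model <- loadModel(model)
  stopifnot(is(model, "TwoStageModel"))
  seqs <- readProteinFasta(queryPath)
  ann <- if (!is.null(hitsPath)) loadDomainHits(hitsPath) else NULL
  pred <- twoStagePredict(seqs, model, ann)
  if (!is.null(out)) {
    df <- pred
    df$stage1_score <- sprintf("%.6f", df$stage1_score)
    df$stage2_score <- ifelse(is.na(df$stage2_score), "NA",
                              sprintf("%.6f", df$stage2_score))
    utils::write.table(df, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeManifest(paste0(out, ".manifest"),
                  list(command = "predict"),
                  c(queryPath, hitsPath))
    return(invisible(pred))
  }
  pred
}

#' Train the reference two-stage predictor on synthetic presets
#'
#' Convenience wrapper: generates the stage-1 and stage-2 presets, trains
#' the hybrid2 pipeline for each stage and bundles the cascade.
#'
#' @param seed integer seed for generation and training.
#' @param thresholds decision thresholds for the two stages.
#' @return list with \code{model} (\code{TwoStageModel}) and the two
#'   generated benchmark datasets.
#' @export
trainSyntheticTwoStage <- function(seed = 1L, thresholds = c(0, 0)) {
  g1 <- generateDataset("stage1", seed = seed)
  g2 <- generateDataset("stage2", seed = seed + 1L)
  m1 <- trainStageModel(g1$dataset, pipelineConfig("hybrid2", "stage1"),
                        g1$annotation, seed = seed)
  m2 <- trainStageModel(g2$dataset, pipelineConfig("hybrid2", "stage2"),
                        g2$annotation, seed = seed)
  list(model = twoStageModel(m1, m2, thresholds),
       stage1 = g1, stage2 = g2)
}
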