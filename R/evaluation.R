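#' Stratified k-fold assignment
#'
#' Randomly assigns every sequence to one of k folds so that, within each
#' class, fold sizes differ by at most one. Deterministic for a fixed
#' seed.
#'
#' @param ds a \code{LabeledProteinSet}.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..k, named by sequence id.
#' @export
makeFolds <- function(ds, k = 5, seed = 1L) {
  makeFoldsFromLabels(classLabels(ds), k, seed)
}

#' @rdname makeFolds
#' @param labels named 0/1 vector (alternative entry point for raw
#'   matrices).
#' @export
makeFoldsFromLabels <- function(labels, k = 5, seed = 1L) {
  if (is.null(names(labels))) stop("labels must be named by sequence id")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < k))
    stop(sprintf("each class needs at least k=%d members (have %d/%d)",
                 k, counts[[1]], counts[[2]]))
  folds <- withSeed(seed, {
    out <- integer(length(labels))
    names(out) <- names(labels)
    for (cls in c(1L, 0L)) {
      ids <- names(labels)[labels == cls]
      out[sample(ids)] <- rep(seq_len(k), length.out = length(ids))
    }
    out
  })
  folds
}

#' Tally a 2x2 confusion table
#'
#' @param labels true 0/1 labels.
#' @param predictions predicted 0/1 labels, same length.
#' @return named integer vector with elements TP, TN, FP, FN.
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (!length(labels)) stop("cannot tally an empty prediction set")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  c(TP = sum(labels == 1L & predictions == 1L),
    TN = sum(labels == 0L & predictions == 0L),
    FP = sum(labels == 0L & predictions == 1L),
    FN = sum(labels == 1L & predictions == 0L))
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Computes
#' \deqn{Sn = 100\,TP/(TP+FN),\quad Sp = 100\,TN/(TN+FP),}
#' \deqn{Acc = 100\,(TP+TN)/(TP+TN+FP+FN),}
#' \deqn{MCC = \frac{TP\cdot TN - FP\cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' A metric whose denominator is zero is reported as \code{NA} (undefined,
#' distinct from 0), except the MCC, whose zero denominator yields 0 by
#' convention. Values are full precision; round only for presentation.
#'
#' @param counts named vector with TP, TN, FP, FN (as from
#'   \code{\link{confusionCounts}}).
#' @return named numeric vector: sensitivity, specificity, accuracy
#'   (percent) and mcc.
#' @export
classMetrics <- function(counts) {
  need <- c("TP", "TN", "FP", "FN")
  if (!all(need %in% names(counts)))
    stop("counts must contain TP, TN, FP and FN")
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
  total <- tp + tn + fp + fn
  if (total == 0) stop("all counts are zero")
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / total
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  c(sensitivity = sens, specificity = spec, accuracy = acc, mcc = mcc)
}

## k-fold CV of an SVM on a prebuilt feature matrix
cvMatrix <- function(X, y, folds, kernel = "radial", cost = 1, gamma = NULL,
                     threshold = 0, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  ids <- rownames(X)
  if (is.null(ids)) {
    ids <- as.character(seq_len(nrow(X)))
    rownames(X) <- ids
  }
  if (!all(ids %in% names(folds)))
    stop("fold assignment must cover every row of X")
  f <- folds[ids]
  k <- max(f)
  perFold <- vector("list", k)
  pooled <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  dvAll <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_len(k)) {
    test <- f == i
    if (length(unique(y[!test])) < 2L)
      stop(sprintf("training partition of fold %d contains a single class", i))
    m <- trainSVM(X[!test, , drop = FALSE], y[!test], kernel = kernel,
                  cost = cost, gamma = gamma, seed = seed)
    dv <- decisionValues(m, X[test, , drop = FALSE])
    dvAll[test] <- dv
    counts <- confusionCounts(y[test], as.integer(dv >= threshold))
    pooled <- pooled + counts
    perFold[[i]] <- c(fold = i, counts, classMetrics(counts))
  }
  perFold <- as.data.frame(do.call(rbind, perFold))
  list(perFold = perFold,
       mean = colMeans(perFold[, c("sensitivity", "specificity",
                                   "accuracy", "mcc")]),
       pooled = classMetrics(pooled),
       pooledCounts = pooled,
       decisionValues = dvAll)
}

#' Cross-validate a feature pipeline
#'
#' Runs stratified k-fold cross-validation of an SVM over the feature
#' matrix produced by a pipeline configuration. Reports per-fold metrics,
#' their unweighted mean (the headline figures), and metrics of the pooled
#' confusion counts, labeled separately.
#'
#' @param ds a \code{LabeledProteinSet}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param ann \code{DomainAnnotation}, required for domain/hybrid modes.
#' @param folds optional precomputed fold assignment (shared splits make
#'   approach comparisons paired); default \code{makeFolds(ds, k, seed)}.
#' @param k,seed folds and seed when \code{folds} is NULL.
#' @return list with \code{perFold} (data.frame), \code{mean},
#'   \code{pooled}, \code{pooledCounts} and per-sequence held-out
#'   \code{decisionValues}.
#' @export
crossValidate <- function(ds, config, ann = NULL, folds = NULL,
                          k = 5, seed = 1L) {
  X <- buildFeatureMatrix(ds, config, ann)
  if (is.null(folds)) folds <- makeFolds(ds, k, seed)
  cvMatrix(X, classLabels(ds), folds, kernel = config$kernel,
           cost = config$cost, gamma = config$gamma,
           threshold = config$threshold, seed = seed)
}

#' Evaluate a fitted model over a grid of decision thresholds
#'
#' One metrics row per threshold, ascending; a sequence is predicted
#' positive when its decision value is at or above the threshold, so
#' sensitivity is non-increasing and specificity non-decreasing along the
#' sweep. The default grid is -1.0 to 1.0 in steps of 0.1.
#'
#' @param model an \code{SVMModel}.
#' @param X feature matrix matching the model's spec.
#' @param y true 0/1 labels.
#' @param thresholds numeric vector of thresholds.
#' @return data.frame: threshold, TP, TN, FP, FN, sensitivity,
#'   specificity, accuracy, mcc.
#' @export
thresholdSweep <- function(model, X, y, thresholds = seq(-1, 1, by = 0.1)) {
  if (!length(thresholds)) stop("thresholds must be non-empty")
  dv <- decisionValues(model, X)
  sweepFromScores(dv, y, thresholds)
}

#' @rdname thresholdSweep
#' @param scores precomputed decision values (alternative entry point).
#' @export
sweepFromScores <- function(scores, y, thresholds = seq(-1, 1, by = 0.1)) {
  if (!length(thresholds)) stop("thresholds must be non-empty")
  y <- as.integer(y)
  rows <- lapply(sort(thresholds), function(t) {
    counts <- confusionCounts(y, as.integer(scores >= t))
    c(threshold = t, counts, classMetrics(counts))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Receiver operating characteristic curve and area
#'
#' Points at every distinct decision value (tied values grouped), plus the
#' corners (0,0) and (1,1); the area is computed by the trapezoidal rule
#' and equals the normalized Mann-Whitney U statistic.
#'
#' @param scores numeric decision values.
#' @param labels true 0/1 labels; both classes must be present.
#' @return list with \code{points} (data.frame: fpr, tpr) and \code{auc}.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("ROC requires both classes to be present")
  o <- order(scores, decreasing = TRUE)
  ys <- labels[o]
  ends <- cumsum(rle(scores[o])$lengths)
  tpr <- c(0, cumsum(ys == 1L)[ends] / P)
  fpr <- c(0, cumsum(ys == 0L)[ends] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Round a metrics row for presentation
#'
#' Percents and MCC rounded to 2 decimals, matching the package's table
#' output convention.
#'
#' @param x named numeric vector or data.frame of metrics.
#' @return same shape, rounded.
#' @export
presentMetrics <- function(x) {
  cols <- c("sensitivity", "specificity", "accuracy", "mcc", "threshold")
  if (is.data.frame(x)) {
    for (cn in intersect(cols, colnames(x))) x[[cn]] <- round(x[[cn]], 2)
    x
  } else round(x, 2)
}

#' Write an evaluation table as TSV
#'
#' Mirrors the threshold-sweep layout (Threshold, Sensitivity,
#' Specificity, Accuracy, MCC) when a threshold column is present.
#'
#' @param report data.frame of metrics rows.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReportTSV <- function(report, path) {
  utils::write.table(presentMetrics(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
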