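## md5 of the serialized training data, for the model's provenance record
hashTrainingData <- function(X, y) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(unname(X), unname(as.integer(y))), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Train a soft-margin SVM classifier
#'
#' Fits a support vector machine on a numeric feature matrix with binary
#' labels. Features enter the kernel as-is (composition percentages and
#' 0/1 domain bits; no rescaling), so a stored model and a feature matrix
#' built from the same spec are always commensurable. The radial basis
#' function kernel is the default, with
#' \eqn{K(u,v) = \exp(-\gamma ||u-v||^2)}.
#'
#' @param X numeric feature matrix (rows = sequences, named columns).
#' @param y binary labels (0/1), parallel to rows of \code{X}.
#' @param kernel \code{"radial"} (default), \code{"linear"} or
#'   \code{"polynomial"}.
#' @param cost soft-margin regularization weight C (default 1).
#' @param gamma RBF/polynomial width; default \code{1/ncol(X)}.
#' @param degree polynomial degree (polynomial kernel only).
#' @param seed integer recorded with the model; fitting itself is
#'   deterministic for fixed inputs.
#' @param positiveName,negativeName class names stored with the model.
#' @param featureConfig optional list describing the feature pipeline that
#'   produced \code{X} (used by \code{\link{twoStagePredict}}).
#' @return an \code{\link{SVMModel}}.
#' @export
trainSVM <- function(X, y, kernel = c("radial", "linear", "polynomial"),
                     cost = 1, gamma = NULL, degree = 3, seed = 1L,
                     positiveName = "positive", negativeName = "negative",
                     featureConfig = list()) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column (feature) names")
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (any(!y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop("training requires both classes to be present")
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  yf <- factor(ifelse(y == 1L, "pos", "neg"), levels = c("neg", "pos"))
  fit <- withSeed(seed, e1071::svm(
    X, yf, kernel = kernel, cost = cost, gamma = gamma, degree = degree,
    scale = FALSE))
  raw <- attr(stats::predict(fit, X, decision.values = TRUE),
              "decision.values")[, 1]
  flip <- mean(raw[y == 1L]) < mean(raw[y == 0L])
  new("SVMModel", fit = fit, kernel = kernel,
      featureNames = colnames(X),
      params = list(cost = cost, gamma = gamma,
                    degree = if (kernel == "polynomial") degree else NULL),
      positiveName = positiveName, negativeName = negativeName,
      flipSign = flip,
      metadata = list(seed = as.integer(seed), date = format(Sys.time()),
                      n = nrow(X), dataHash = hashTrainingData(X, y),
                      featureConfig = featureConfig))
}

checkFeatureSpec <- function(object, X) {
  X <- as.matrix(X)
  if (!identical(colnames(X), object@featureNames)) {
    missing <- setdiff(object@featureNames, colnames(X))
    extra <- setdiff(colnames(X), object@featureNames)
    msg <- if (length(missing) || length(extra))
      sprintf("missing: %s; unexpected: %s",
              paste(missing, collapse = ", "),
              paste(extra, collapse = ", "))
    else "same names, different order"
    stop(sprintf("feature spec mismatch between model and matrix (%s)", msg))
  }
  X
}

#' @rdname decisionValues
#' @export
setMethod("decisionValues", "SVMModel", function(object, X) {
  X <- checkFeatureSpec(object, X)
  if (!nrow(X)) return(numeric(0))
  raw <- attr(stats::predict(object@fit, X, decision.values = TRUE),
              "decision.values")[, 1]
  out <- if (object@flipSign) -raw else raw
  stats::setNames(unname(out), rownames(X))
})

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "SVMModel", function(object, X, threshold = 0) {
  dv <- decisionValues(object, X)
  stats::setNames(as.integer(dv >= threshold), names(dv))
})

#' Grid search over SVM hyperparameters by cross-validated accuracy
#'
#' Evaluates every (cost, gamma) pair on the grid by stratified k-fold
#' cross-validation and returns the pair with the best mean accuracy,
#' breaking ties by mean MCC, then by smaller cost and gamma. The search
#' is reproducible under a fixed seed.
#'
#' @param X feature matrix; @param y binary labels.
#' @param costs candidate C values (default 0.1, 1, 10, 100).
#' @param gammas candidate RBF widths (default powers of two, 2^-7..2^3).
#' @param k folds (default 5); @param seed fold-split seed.
#' @param kernel kernel passed to \code{\link{trainSVM}}.
#' @return list with \code{cost}, \code{gamma} and the full results
#'   \code{grid} (data.frame: cost, gamma, accuracy, mcc).
#' @export
tuneSVM <- function(X, y, costs = c(0.1, 1, 10, 100), gammas = 2^(-7:3),
                    k = 5, seed = 1L, kernel = "radial") {
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  folds <- makeFoldsFromLabels(stats::setNames(as.integer(y), ids), k, seed)
  grid <- expand.grid(cost = costs, gamma = gammas)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- cvMatrix(X, y, folds, kernel = kernel, cost = grid$cost[i],
                  gamma = grid$gamma[i], seed = seed)
    c(accuracy = r$mean[["accuracy"]], mcc = r$mean[["mcc"]])
  })
  res <- do.call(rbind, res)
  grid$accuracy <- res[, "accuracy"]; grid$mcc <- res[, "mcc"]
  ord <- order(-grid$accuracy, -grid$mcc, grid$cost, grid$gamma)
  best <- grid[ord[1], ]
  list(cost = best$cost, gamma = best$gamma, grid = grid)
}

#' Persist and restore fitted models
#'
#' Models are written with \code{saveRDS}; the stored object carries the
#' exact feature-name order, kernel, hyperparameters and a hash of the
#' training data, without which scoring would be undefined.
#'
#' @param model an \code{SVMModel} or \code{TwoStageModel}.
#' @param path file path.
#' @return \code{path} (save) or the restored model (load).
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "SVMModel") || is(model, "TwoStageModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!(is(model, "SVMModel") || is(model, "TwoStageModel")))
    stop(sprintf("%s does not contain a saved model", path))
  validObject(model)
  model
}

#' Linear-SVM feature weights
#'
#' For a linear-kernel model, the primal weight vector
#' \eqn{w = \sum_i \alpha_i y_i x_i}, oriented so that positive weights
#' favor the positive class.
#'
#' @param model a linear-kernel \code{SVMModel}.
#' @return named numeric vector of weights.
#' @export
linearWeights <- function(model) {
  stopifnot(is(model, "SVMModel"))
  if (model@kernel != "linear")
    stop("feature weights are only defined for the linear kernel")
  w <- drop(t(model@fit$coefs) %*% model@fit$SV)
  if (model@flipSign) w <- -w
  stats::setNames(w, model@featureNames)
}
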