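## SVM and random-forest baselines behind the same predictProba/predictLabel
## generics as the neural classifier, plus k-fold cross-validation.

#' Baseline configuration
#'
#' SVM: polynomial kernel with kernel coefficient (gamma) 0.01. Random
#' forest: a minimum leaf weight fraction of 0.1, realised as a minimum
#' terminal-node size of `ceiling(0.1 * n)`. Both are evaluated with
#' stratified 5-fold cross-validation by [crossValidate()].
#'
#' @param svmGamma polynomial-kernel coefficient (default 0.01).
#' @param svmDegree polynomial degree (default 3).
#' @param rfLeafFraction minimum fraction of samples per terminal node
#'   (default 0.1).
#' @param rfTrees number of trees (default 500).
#' @param seed integer seed.
#' @export
baselineConfig <- function(svmGamma = 0.01, svmDegree = 3L,
                           rfLeafFraction = 0.1, rfTrees = 500L, seed = 1L) {
  stopifnot(svmGamma > 0, svmDegree >= 1L, rfLeafFraction > 0,
            rfLeafFraction < 1, rfTrees >= 1L)
  list(svmGamma = svmGamma, svmDegree = as.integer(svmDegree),
       rfLeafFraction = rfLeafFraction, rfTrees = as.integer(rfTrees),
       seed = as.integer(seed))
}

#' Fitted baseline classifier
#'
#' Thin wrapper holding the fitted e1071/randomForest object so the package
#' generics apply uniformly.
#'
#' @slot kind `"svm"` or `"rf"`.
#' @slot fit the underlying fitted model.
#' @slot config the [baselineConfig()] used.
#' @slot schemaHash feature-schema fingerprint ("" if none).
#' @export
setClass("BaselineModel",
         representation(kind = "character", fit = "ANY", config = "list",
                        schemaHash = "character"))

.baselineHash <- function(X) {
  h <- attr(X, "schemaHash")
  if (is.null(h)) "" else h
}

#' Train the SVM baseline
#'
#' `e1071::svm` with a polynomial kernel and kernel coefficient 0.01 on
#' pre-standardized features (internal scaling disabled).
#'
#' @param X standardized feature matrix.
#' @param y binary 0/1 labels (both classes present).
#' @param config from [baselineConfig()].
#' @return a [BaselineModel-class].
#' @export
trainSvmBaseline <- function(X, y, config = baselineConfig()) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("need both classes to fit", call. = FALSE)
  set.seed(config$seed)
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "polynomial",
                    gamma = config$svmGamma, degree = config$svmDegree,
                    scale = FALSE)
  new("BaselineModel", kind = "svm", fit = fit, config = config,
      schemaHash = .baselineHash(X))
}

#' Train the random-forest baseline
#'
#' `randomForest` with the minimum-leaf-weight constraint mapped to
#' `nodesize = ceiling(rfLeafFraction * n)`.
#'
#' @inheritParams trainSvmBaseline
#' @export
trainRfBaseline <- function(X, y, config = baselineConfig()) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("need both classes to fit", call. = FALSE)
  set.seed(config$seed)
  fit <- randomForest::randomForest(
    X, factor(y, levels = c(0, 1)), ntree = config$rfTrees,
    nodesize = ceiling(config$rfLeafFraction * nrow(X)))
  new("BaselineModel", kind = "rf", fit = fit, config = config,
      schemaHash = .baselineHash(X))
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "BaselineModel", function(model, X) {
  X <- as.matrix(X)
  if (model@kind == "svm") {
    dv <- attr(stats::predict(model@fit, X, decision.values = TRUE),
               "decision.values")[, 1L]
    ## decision values are signed distances for the first factor level ("0");
    ## flip so larger score means class 1, then squash to [0, 1]
    sigmoid(-dv)
  } else {
    stats::predict(model@fit, X, type = "prob")[, "1"]
  }
})

#' @rdname predictLabel
#' @export
setMethod("predictLabel", "BaselineModel", function(model, X, threshold = 0.5) {
  X <- as.matrix(X)
  if (threshold == 0.5) {
    as.integer(as.character(stats::predict(model@fit, X)))
  } else {
    as.integer(predictProba(model, X) >= threshold)
  }
})

#' @describeIn BaselineModel-class compact display.
#' @param object a `BaselineModel`.
#' @export
setMethod("show", "BaselineModel", function(object) {
  cat(sprintf("BaselineModel(%s)\n", object@kind))
})

#' Stratified k-fold cross-validation
#'
#' Builds and evaluates a classifier on each stratified fold and aggregates
#' the six confusion-matrix metrics as unweighted mean and standard
#' deviation across folds.
#'
#' @param builder function(X, y) returning a fitted model answering
#'   [predictLabel()].
#' @param X feature matrix.
#' @param y binary 0/1 labels.
#' @param nFolds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list with `folds` (per-fold metric rows), `mean` and `sd`
#'   (named numeric vectors over the six metrics).
#' @export
crossValidate <- function(builder, X, y, nFolds = 5L, seed = 1L) {
  X <- as.matrix(X)
  folds <- stratifiedKfold(y, nFolds = nFolds, seed = seed)
  rows <- lapply(folds, function(f) {
    fit <- builder(X[f$train, , drop = FALSE], y[f$train])
    pred <- predictLabel(fit, X[f$test, , drop = FALSE])
    unlist(classificationMetrics(confusionCounts(y[f$test], pred)))
  })
  tab <- do.call(rbind, rows)
  list(folds = as.data.frame(tab),
       mean = colMeans(tab),
       sd = apply(tab, 2, stats::sd))
}
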