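## Confusion-matrix metrics (accuracy, precision, recall/sensitivity, F1,
## specificity as percentages; MCC in [-1, 1]), PR/ROC curve data and the
## per-epoch validation-curve report.

#' Confusion matrix counts
#'
#' @slot TP,TN,FP,FN nonnegative integer counts, summing to n > 0.
#' @export
setClass("ConfusionMatrix",
         representation(TP = "integer", TN = "integer",
                        FP = "integer", FN = "integer"),
         validity = function(object) {
           v <- c(object@TP, object@TN, object@FP, object@FN)
           if (any(v < 0)) return("counts must be nonnegative")
           if (sum(v) == 0) return("empty confusion matrix")
           TRUE
         })

#' Build a confusion matrix from truth and prediction
#'
#' @param yTrue,yPred equal-length binary 0/1 vectors.
#' @return a [ConfusionMatrix-class].
#' @export
confusionCounts <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("length mismatch between truth and prediction", call. = FALSE)
  if (!all(yTrue %in% c(0, 1)) || !all(yPred %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  new("ConfusionMatrix",
      TP = sum(yTrue == 1 & yPred == 1), TN = sum(yTrue == 0 & yPred == 0),
      FP = sum(yTrue == 0 & yPred == 1), FN = sum(yTrue == 1 & yPred == 0))
}

#' @describeIn ConfusionMatrix-class display as a 2x2 table.
#' @param object a `ConfusionMatrix`.
#' @export
setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@TP, object@FN, object@FP, object@TN), 2, 2,
              dimnames = list(truth = c("1", "0"), predicted = c("1", "0")))
  print(m)
})

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall (= sensitivity), F1 and specificity as
#' percentages; the Matthews correlation coefficient on its natural [-1, 1]
#' scale. Degenerate denominators are defined: precision is 0 (with a
#' warning) when nothing is predicted positive, and MCC is 0 when its
#' denominator vanishes.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return named list: accuracy, precision, recall, f1, specificity
#'   (percent), mcc.
#' @export
classificationMetrics <- function(cm) {
  TP <- as.numeric(cm@TP); TN <- as.numeric(cm@TN)
  FP <- as.numeric(cm@FP); FN <- as.numeric(cm@FN)
  n <- TP + TN + FP + FN
  accuracy <- (TP + TN) / n * 100
  precision <- if (TP + FP == 0) {
    warning("no positive predictions; precision set to 0", call. = FALSE)
    0
  } else TP / (TP + FP) * 100
  recall <- if (TP + FN == 0) 0 else TP / (TP + FN) * 100
  specificity <- if (TN + FP == 0) 0 else TN / (TN + FP) * 100
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, specificity = specificity, mcc = mcc)
}

.checkScores <- function(yTrue, scores) {
  if (length(yTrue) != length(scores))
    stop("length mismatch", call. = FALSE)
  if (!all(yTrue %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  if (length(unique(yTrue)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
}

#' ROC curve and area
#'
#' Sweeps the threshold over the unique scores and returns (FPR, TPR) points
#' with the trapezoidal area. The area equals the probability that a random
#' positive scores above a random negative (ties counted half).
#'
#' @param yTrue binary 0/1 truth, both classes present.
#' @param scores predicted probabilities in [0, 1].
#' @return list with `points` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
rocCurve <- function(yTrue, scores) {
  .checkScores(yTrue, scores)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  nPos <- sum(yTrue == 1); nNeg <- sum(yTrue == 0)
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & yTrue == 0) / nNeg, tpr = sum(pred & yTrue == 1) / nPos)
  }, numeric(2)))
  auc <- sum(diff(pts[, "fpr"]) * (utils::head(pts[, "tpr"], -1) +
                                     utils::tail(pts[, "tpr"], -1)) / 2)
  list(points = data.frame(fpr = pts[, "fpr"], tpr = pts[, "tpr"],
                           threshold = thr),
       auc = auc)
}

#' Precision-recall curve and area
#'
#' Threshold sweep over unique scores; the area is the trapezoid over
#' (recall, precision). The point at threshold above all scores (recall 0)
#' takes the precision of the highest-score threshold.
#'
#' @inheritParams rocCurve
#' @return list with `points` (recall, precision, threshold) and `auc`.
#' @export
prCurve <- function(yTrue, scores) {
  .checkScores(yTrue, scores)
  thr <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(yTrue == 1)
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    tp <- sum(pred & yTrue == 1)
    c(recall = tp / nPos,
      precision = if (sum(pred) == 0) 1 else tp / sum(pred))
  }, numeric(2)))
  pts <- rbind(c(0, pts[1L, "precision"]), pts)
  thr <- c(Inf, thr)
  auc <- sum(diff(pts[, 1L]) * (utils::head(pts[, 2L], -1) +
                                  utils::tail(pts[, 2L], -1)) / 2)
  list(points = data.frame(recall = pts[, 1L], precision = pts[, 2L],
                           threshold = thr),
       auc = auc)
}

#' Per-epoch validation-curve table
#'
#' Reshapes a training history into the table backing the per-epoch
#' training-versus-validation accuracy curve, optionally writing it as CSV.
#'
#' @param history data.frame from [trainingHistory()] with columns epoch,
#'   train_acc, val_acc, loss.
#' @param path optional CSV output path.
#' @return the table, invisibly if written to `path`.
#' @export
validationCurveReport <- function(history, path = NULL) {
  if (!is.data.frame(history) || nrow(history) == 0L)
    stop("empty training history", call. = FALSE)
  need <- c("epoch", "train_acc", "val_acc", "loss")
  if (!all(need %in% names(history)))
    stop("history must have columns epoch, train_acc, val_acc, loss",
         call. = FALSE)
  tab <- history[order(history$epoch), need]
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
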