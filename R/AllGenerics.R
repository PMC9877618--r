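#' Predicted class-1 probabilities
#'
#' @param model a trained classifier ([StressNet-class] or
#'   [BaselineModel-class]).
#' @param X feature matrix matching the schema the model was trained on.
#' @return numeric probabilities in [0, 1].
#' @export
setGeneric("predictProba", function(model, X) standardGeneric("predictProba"))

#' Thresholded class labels
#'
#' Label 1 wherever the predicted probability is at or above the threshold.
#'
#' @inheritParams predictProba
#' @param threshold decision threshold (default 0.5).
#' @return integer 0/1 labels.
#' @export
setGeneric("predictLabel",
           function(model, X, threshold = 0.5) standardGeneric("predictLabel"))
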