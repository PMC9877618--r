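## The neural classifier: 46 -> 150 -> 50 -> 1 with a selectable activation
## (SIELU by default), He-normal initialisation, dropout after the hidden
## layer, a sigmoid output unit, Adam optimisation and MSE-on-sigmoid loss.
## Two input-layer interpretations are provided: "dense" (plain feed-forward)
## and "recurrent-length-1" (a one-step LSTM cell consuming each feature
## vector as a length-1 sequence; with zero initial state the cell reduces to
## h = o * act(i * g), a gated feed-forward map). Everything is hand-rolled
## matrix algebra so training is exactly reproducible under a seed.

#' Network configuration
#'
#' Defaults follow the reference architecture: a 150-unit input layer with
#' He-normal initialisation and the SIELU activation, a 50-unit hidden layer
#' with 0.02 dropout, a single sigmoid output unit, Adam
#' (\eqn{\alpha=10^{-3}, \beta_1=0.9, \beta_2=0.999, \epsilon=10^{-8}}),
#' mean-square-error loss and 500 epochs. `inputMode` selects how the input
#' layer consumes the 46 features: `"recurrent-length-1"` (default; a
#' degenerate one-step LSTM cell) or `"dense"`.
#'
#' @param nFeatures number of input features (46 for the standard schema).
#' @param inputUnits,hiddenUnits layer widths.
#' @param activation one of `"sielu"`, `"gelu"`, `"relu"`, `"tanh"`,
#'   `"sigmoid"`, applied in the input and hidden layers.
#' @param dropoutRate dropout after the hidden layer, in [0, 1).
#' @param loss `"mse"` (default) or `"bce"`.
#' @param epochs,batchSize training schedule.
#' @param learningRate,beta1,beta2,epsilon Adam parameters.
#' @param inputMode `"recurrent-length-1"` or `"dense"`.
#' @param seed integer seed governing initialisation, batch order and dropout.
#' @return validated configuration list.
#' @export
modelConfig <- function(nFeatures = 46L, inputUnits = 150L, hiddenUnits = 50L,
                        activation = "sielu", dropoutRate = 0.02,
                        loss = c("mse", "bce"), epochs = 500L, batchSize = 32L,
                        learningRate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8,
                        inputMode = c("recurrent-length-1", "dense"),
                        seed = 1L) {
  loss <- match.arg(loss)
  inputMode <- match.arg(inputMode)
  .activation(activation)  # errors on unknown name
  stopifnot(nFeatures >= 1L, inputUnits >= 1L, hiddenUnits >= 1L,
            dropoutRate >= 0, dropoutRate < 1, epochs >= 1L, batchSize >= 1L,
            learningRate > 0)
  list(nFeatures = as.integer(nFeatures), inputUnits = as.integer(inputUnits),
       hiddenUnits = as.integer(hiddenUnits), activation = activation,
       dropoutRate = dropoutRate, loss = loss, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), learningRate = learningRate,
       beta1 = beta1, beta2 = beta2, epsilon = epsilon,
       inputMode = inputMode, seed = as.integer(seed))
}

#' Trained or untrained network
#'
#' @slot config configuration list from [modelConfig()].
#' @slot weights named list of weight matrices and bias vectors.
#' @slot history per-epoch data.frame (epoch, train_acc, val_acc, loss);
#'   empty until trained.
#' @slot schemaHash hash of the feature schema the model expects ("" if the
#'   training matrix carried none).
#' @export
setClass("StressNet",
         representation(config = "list", weights = "list",
                        history = "data.frame", schemaHash = "character"))

.heDraw <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

#' Build an untrained network
#'
#' Draws all weights from He-normal distributions (variance 2/fan-in) under
#' `config$seed`; biases start at zero. The same seed always yields the same
#' initial weights.
#'
#' @param config from [modelConfig()].
#' @return an untrained [StressNet-class].
#' @export
buildNetwork <- function(config) {
  set.seed(config$seed)
  f <- config$nFeatures; u1 <- config$inputUnits; u2 <- config$hiddenUnits
  w <- if (config$inputMode == "dense") {
    list(W1 = .heDraw(f, u1), b1 = numeric(u1))
  } else {
    list(Wi = .heDraw(f, u1), bi = numeric(u1),
         Wo = .heDraw(f, u1), bo = numeric(u1),
         Wg = .heDraw(f, u1), bg = numeric(u1))
  }
  w <- c(w, list(W2 = .heDraw(u1, u2), b2 = numeric(u2),
                 W3 = .heDraw(u2, 1L), b3 = numeric(1L)))
  new("StressNet", config = config, weights = w,
      history = data.frame(), schemaHash = "")
}

#' Number of trainable parameters
#'
#' @param model a [StressNet-class].
#' @export
parameterCount <- function(model) sum(vapply(model@weights, length, integer(1)))

.addBias <- function(Z, b) sweep(Z, 2, b, "+")

## forward pass; returns caches needed for backprop. mask: dropout mask or NULL.
.forward <- function(w, cfg, X, mask = NULL) {
  act <- .activation(cfg$activation)
  cache <- list(X = X)
  if (cfg$inputMode == "dense") {
    cache$Z1 <- .addBias(X %*% w$W1, w$b1)
    A1 <- act$f(cache$Z1)
  } else {
    cache$Zi <- .addBias(X %*% w$Wi, w$bi); cache$I <- sigmoid(cache$Zi)
    cache$Zo <- .addBias(X %*% w$Wo, w$bo); cache$O <- sigmoid(cache$Zo)
    cache$Zg <- .addBias(X %*% w$Wg, w$bg); cache$G <- act$f(cache$Zg)
    cache$Cc <- cache$I * cache$G
    A1 <- cache$O * act$f(cache$Cc)
  }
  cache$A1 <- A1
  cache$Z2 <- .addBias(A1 %*% w$W2, w$b2)
  A2 <- act$f(cache$Z2)
  if (!is.null(mask)) A2 <- A2 * mask / (1 - cfg$dropoutRate)
  cache$A2 <- A2
  cache$Z3 <- .addBias(A2 %*% w$W3, w$b3)
  cache$P <- sigmoid(cache$Z3)
  cache
}

.backward <- function(w, cfg, cache, y, mask = NULL) {
  act <- .activation(cfg$activation)
  n <- length(y)
  P <- cache$P
  dZ3 <- if (cfg$loss == "mse") (2 / n) * (P - y) * P * (1 - P)
         else (P - y) / n
  g <- list(W3 = t(cache$A2) %*% dZ3, b3 = colSums(dZ3))
  dA2 <- dZ3 %*% t(w$W3)
  if (!is.null(mask)) dA2 <- dA2 * mask / (1 - cfg$dropoutRate)
  dZ2 <- dA2 * act$g(cache$Z2)
  g$W2 <- t(cache$A1) %*% dZ2; g$b2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(w$W2)
  if (cfg$inputMode == "dense") {
    dZ1 <- dA1 * act$g(cache$Z1)
    g$W1 <- t(cache$X) %*% dZ1; g$b1 <- colSums(dZ1)
  } else {
    dO <- dA1 * act$f(cache$Cc)
    dZo <- dO * cache$O * (1 - cache$O)
    dCc <- dA1 * cache$O * act$g(cache$Cc)
    dZi <- dCc * cache$G * cache$I * (1 - cache$I)
    dZg <- dCc * cache$I * act$g(cache$Zg)
    g$Wi <- t(cache$X) %*% dZi; g$bi <- colSums(dZi)
    g$Wo <- t(cache$X) %*% dZo; g$bo <- colSums(dZo)
    g$Wg <- t(cache$X) %*% dZg; g$bg <- colSums(dZg)
  }
  g[names(w)]
}

.lossValue <- function(cfg, P, y) {
  if (cfg$loss == "mse") mean((P - y)^2)
  else {
    eps <- 1e-12
    -mean(y * log(P + eps) + (1 - y) * log(1 - P + eps))
  }
}

#' Train the network
#'
#' Runs exactly `config$epochs` epochs of mini-batch Adam (no early
#' stopping), recording training accuracy, validation accuracy and training
#' loss after every epoch. Batch order and dropout masks are drawn from the
#' seeded RNG stream, so training is bit-reproducible.
#'
#' @param model untrained [StressNet-class] from [buildNetwork()].
#' @param X,y training matrix (rows = samples) and binary 0/1 labels.
#' @param Xval,yval validation split for the per-epoch curve.
#' @return the trained [StressNet-class] with a filled `history`.
#' @export
trainNetwork <- function(model, X, y, Xval, yval) {
  cfg <- model@config
  X <- as.matrix(X); Xval <- as.matrix(Xval)
  if (ncol(X) != cfg$nFeatures)
    stop(sprintf("expected %d features, got %d", cfg$nFeatures, ncol(X)),
         call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  hash <- attr(X, "schemaHash")
  w <- model@weights
  adam <- list(m = lapply(w, function(p) p * 0),
               v = lapply(w, function(p) p * 0), t = 0)
  set.seed(cfg$seed + 1L)
  n <- nrow(X)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batchSize)) {
      idx <- ord[start:min(start + cfg$batchSize - 1L, n)]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      mask <- if (cfg$dropoutRate > 0)
        matrix(stats::rbinom(length(idx) * cfg$hiddenUnits, 1L,
                             1 - cfg$dropoutRate),
               length(idx), cfg$hiddenUnits)
      cache <- .forward(w, cfg, Xb, mask)
      grads <- .backward(w, cfg, cache, yb, mask)
      adam$t <- adam$t + 1
      for (nm in names(w)) {
        adam$m[[nm]] <- cfg$beta1 * adam$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
        adam$v[[nm]] <- cfg$beta2 * adam$v[[nm]] + (1 - cfg$beta2) * grads[[nm]]^2
        mhat <- adam$m[[nm]] / (1 - cfg$beta1^adam$t)
        vhat <- adam$v[[nm]] / (1 - cfg$beta2^adam$t)
        w[[nm]] <- w[[nm]] - cfg$learningRate * mhat / (sqrt(vhat) + cfg$epsilon)
      }
    }
    pTrain <- .forward(w, cfg, X)$P
    loss <- .lossValue(cfg, pTrain, y)
    if (!is.finite(loss))
      stop(sprintf("non-finite loss at epoch %d; try a smaller learning rate", ep),
           call. = FALSE)
    pVal <- .forward(w, cfg, Xval)$P
    hist[[ep]] <- data.frame(
      epoch = ep,
      train_acc = mean((pTrain >= 0.5) == y),
      val_acc = mean((pVal >= 0.5) == yval),
      loss = loss)
  }
  methods::initialize(model, weights = w, history = do.call(rbind, hist),
                      schemaHash = if (is.null(hash)) "" else hash)
}

.checkSchema <- function(model, X) {
  hx <- attr(X, "schemaHash")
  if (nzchar(model@schemaHash) && !is.null(hx) && !identical(hx, model@schemaHash))
    stop(sprintf("feature schema mismatch: model expects hash %s",
                 model@schemaHash), call. = FALSE)
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "StressNet", function(model, X) {
  X <- as.matrix(X)
  .checkSchema(model, X)
  if (ncol(X) != model@config$nFeatures)
    stop(sprintf("expected %d features, got %d",
                 model@config$nFeatures, ncol(X)), call. = FALSE)
  as.numeric(.forward(model@weights, model@config, X)$P)
})

#' @rdname predictLabel
#' @export
setMethod("predictLabel", "StressNet", function(model, X, threshold = 0.5) {
  as.integer(predictProba(model, X) >= threshold)
})

#' @describeIn StressNet-class per-epoch training history.
#' @param model a `StressNet`.
#' @export
trainingHistory <- function(model) model@history

#' @describeIn StressNet-class compact display.
#' @param object a `StressNet`.
#' @export
setMethod("show", "StressNet", function(object) {
  cfg <- object@config
  cat(sprintf("StressNet %d-%d-%d-1 (%s, %s input), %s\n",
              cfg$nFeatures, cfg$inputUnits, cfg$hiddenUnits, cfg$activation,
              cfg$inputMode,
              if (nrow(object@history)) sprintf("trained %d epochs (final train acc %.3f)",
                                                nrow(object@history),
                                                utils::tail(object@history$train_acc, 1))
              else "untrained"))
})

#' Serialize a model to JSON
#'
#' Stores the configuration, schema hash, weights (full precision) and
#' history in a single portable JSON container; [loadModel()] reproduces
#' predictions bit-identically.
#'
#' @param model a [StressNet-class].
#' @param path output path.
#' @export
saveModel <- function(model, path) {
  obj <- list(
    container = "ProtStress.StressNet", version = 1L,
    config = model@config, schemaHash = model@schemaHash,
    weights = lapply(model@weights, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))),
    history = model@history)
  ## I(17) significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a serialized model
#'
#' @param path path written by [saveModel()].
#' @return a [StressNet-class].
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "ProtStress.StressNet"))
    stop("not a ProtStress model container", call. = FALSE)
  w <- lapply(obj$weights, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1L], p$dim[2L])
    else as.numeric(p$data)
  })
  cfg <- obj$config
  intFields <- c("nFeatures", "inputUnits", "hiddenUnits", "epochs",
                 "batchSize", "seed")
  cfg[intFields] <- lapply(cfg[intFields], as.integer)
  hist <- if (is.null(obj$history) || !length(obj$history)) data.frame()
          else as.data.frame(obj$history)
  new("StressNet", config = cfg, weights = w, history = hist,
      schemaHash = if (is.null(obj$schemaHash)) "" else obj$schemaHash)
}
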