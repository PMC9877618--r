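## Activation functions used by the classifier, all vectorised and overflow-safe.
## SIELU is the package's central primitive: the tanh-form GELU rewritten through
## the identity tanh(y) = 2*sigmoid(2y) - 1, so the two are equal to machine
## precision everywhere.

.checkFinite <- function(x, arg = deparse(substitute(x))) {
  bad <- which(!is.finite(x))
  if (length(bad))
    stop(sprintf("non-finite value in '%s' at position %d (value: %s)",
                 arg, bad[1L], format(x[bad[1L]])), call. = FALSE)
  invisible(x)
}

#' Logistic sigmoid
#'
#' \eqn{f(x) = 1/(1+e^{-x})}, computed in the branch form that never
#' exponentiates a positive argument, so it is overflow-safe for any finite
#' pre-activation.
#'
#' @param x numeric vector of finite values.
#' @return numeric vector in (0, 1).
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(-1000)  # underflows gracefully to 0
#' @export
sigmoid <- function(x) {
  .checkFinite(x, "x")
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  e <- exp(x[!pos])
  out[!pos] <- e / (1 + e)
  attributes(out) <- attributes(x)
  out
}

#' Hyperbolic-tangent activation
#'
#' \eqn{f(x) = 2/(1+e^{-2x}) - 1}, an odd sigmoidal map onto (-1, 1).
#'
#' @inheritParams sigmoid
#' @return numeric vector in (-1, 1).
#' @export
tanhAct <- function(x) {
  .checkFinite(x, "x")
  tanh(x)
}

#' Rectified linear unit
#'
#' \eqn{f(x) = x} for \eqn{x \ge 0}, else 0 (the boundary x = 0 belongs to the
#' identity branch).
#'
#' @inheritParams sigmoid
#' @export
relu <- function(x) {
  .checkFinite(x, "x")
  pmax(x, 0)
}

#' Leaky rectified linear unit
#'
#' \eqn{f(x) = x} for \eqn{x \ge 0}, else \eqn{\sigma x} with a small positive
#' slope so negative pre-activations keep a gradient.
#'
#' @inheritParams sigmoid
#' @param slope positive leak coefficient for the negative branch (default 0.01).
#' @export
leakyRelu <- function(x, slope = 0.01) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope <= 0)
    stop("'slope' must be a single positive number", call. = FALSE)
  .checkFinite(x, "x")
  ifelse(x >= 0, x, slope * x)
}

#' Softmax
#'
#' \eqn{f(x_j) = e^{x_j} / \sum_k e^{x_k}}, computed after subtracting the
#' maximum so arbitrarily large logits do not overflow. Softmax is invariant
#' under a common shift of its inputs.
#'
#' @param v non-empty numeric vector of finite logits.
#' @return probability vector summing to 1.
#' @export
softmax <- function(v) {
  if (length(v) == 0L) stop("softmax of an empty vector", call. = FALSE)
  .checkFinite(v, "v")
  e <- exp(v - max(v))
  e / sum(e)
}

#' Tanh-form Gaussian error linear unit (GELU)
#'
#' \deqn{f(x) = 0.5 x [1 + \tanh(\sqrt{2/\pi}(x + 0.044715 x^3))]}
#'
#' The classical tanh approximation of \eqn{x \Phi(x)}; it deviates from the
#' exact GELU by less than about 5e-4 near |x| = 1.
#'
#' @inheritParams sigmoid
#' @param cubicCoeff cubic coefficient of the inner polynomial (default 0.044715).
#' @param scale scale of the inner polynomial (default \eqn{\sqrt{2/\pi}}).
#' @export
geluTanh <- function(x, cubicCoeff = 0.044715, scale = sqrt(2 / pi)) {
  .checkFinite(x, "x")
  0.5 * x * (1 + tanh(scale * (x + cubicCoeff * x^3)))
}

#' SIELU activation (GELU with sigmoid)
#'
#' \deqn{f(x) = x \, \sigma(2\sqrt{2/\pi}(x + 0.044715 x^3))}
#'
#' Algebraically identical to [geluTanh()] via
#' \eqn{\tanh(y) = 2\sigma(2y) - 1}; expressing the gate through the sigmoid
#' avoids a separate tanh evaluation inside network layers.
#'
#' @inheritParams geluTanh
#' @export
sielu <- function(x, cubicCoeff = 0.044715, scale = sqrt(2 / pi)) {
  .checkFinite(x, "x")
  x * sigmoid(2 * scale * (x + cubicCoeff * x^3))
}

#' Analytic derivative of SIELU
#'
#' With inner polynomial \eqn{u(x) = 2\sqrt{2/\pi}(x + 0.044715x^3)} and
#' \eqn{s = \sigma(u)}: \eqn{f'(x) = s + x\, s(1-s)\, u'(x)}.
#'
#' @inheritParams geluTanh
#' @export
sieluGrad <- function(x, cubicCoeff = 0.044715, scale = sqrt(2 / pi)) {
  .checkFinite(x, "x")
  u  <- 2 * scale * (x + cubicCoeff * x^3)
  du <- 2 * scale * (1 + 3 * cubicCoeff * x^2)
  s  <- sigmoid(u)
  s + x * s * (1 - s) * du
}

## name -> (fn, grad) lookup used by the network layers
.activationTable <- function() {
  list(
    sielu   = list(f = sielu,   g = sieluGrad),
    gelu    = list(f = geluTanh,
                   g = function(x) sieluGrad(x)),  # identical function, identical derivative
    relu    = list(f = relu,    g = function(x) as.numeric(x >= 0)),
    tanh    = list(f = tanhAct, g = function(x) 1 - tanh(x)^2),
    sigmoid = list(f = sigmoid, g = function(x) { s <- sigmoid(x); s * (1 - s) })
  )
}

.activation <- function(name) {
  tab <- .activationTable()
  if (!name %in% names(tab))
    stop(sprintf("unknown activation '%s' (choose one of: %s)",
                 name, paste(names(tab), collapse = ", ")), call. = FALSE)
  tab[[name]]
}
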