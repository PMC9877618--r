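## Historical approximations to the standard normal CDF and quantile from which
## the GELU/SIELU gate descends, plus an error-scan harness that measures each
## approximation against the exact Phi/Phi^-1 on a dense grid.

#' Constants of the classical normal-distribution approximations
#'
#' Three printed constant sets: the 1955 four-constant and six-constant
#' rational quantile approximations, and the later rational inverse-normal
#' form whose absolute error is bounded by 4.5e-4 (its constants coincide
#' with the six-constant set).
#'
#' @return a named list with components `hastings4`, `hastings6`, `asInverse`,
#'   each a named numeric vector.
#' @export
normalApproxConstants <- function() {
  list(
    hastings4 = c(a0 = 2.30753, a1 = 0.27061, b1 = 0.99229, b2 = 0.04481),
    hastings6 = c(a0 = 2.515517, a1 = 0.802853, a2 = 0.010328,
                  b1 = 1.432788, b2 = 0.189269, b3 = 0.001308),
    asInverse = c(C0 = 2.515517, C1 = 0.802853, C2 = 0.010328,
                  d1 = 1.432788, d2 = 0.189269, d3 = 0.001308)
  )
}

#' Exact standard normal CDF
#'
#' High-precision \eqn{\Phi(z)} used as the oracle in error scans; delegates to
#' the vetted erf-based implementation in [stats::pnorm()].
#'
#' @param z numeric vector of finite values.
#' @export
exactNormalCdf <- function(z) {
  .checkFinite(z, "z")
  stats::pnorm(z)
}

## shared tail transform eta = sqrt(ln(1/p^2)) for the rational quantile forms
.tailTransform <- function(p, arg) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 0.5))
    stop(sprintf("'%s' must lie in (0, 0.5] (upper-tail probability)", arg),
         call. = FALSE)
  sqrt(log(1 / p^2))
}

#' Rational approximation to the upper-tail normal quantile
#'
#' For an upper-tail probability \eqn{p \in (0, 0.5]}, with
#' \eqn{t = \sqrt{\ln(1/p^2)}}:
#' \deqn{z \approx t - \frac{C_0 + C_1 t + C_2 t^2}{1 + d_1 t + d_2 t^2 + d_3 t^3}}
#' whose absolute error satisfies \eqn{|e(p)| < 4.5\times 10^{-4}}.
#'
#' @param p upper-tail probability in (0, 0.5]; vectorised.
#' @param constants constant list as from [normalApproxConstants()].
#' @return approximation to \eqn{\Phi^{-1}(1-p)}.
#' @export
inverseNormalRational <- function(p, constants = normalApproxConstants()) {
  t <- .tailTransform(p, "p")
  k <- constants$asInverse
  t - (k[["C0"]] + k[["C1"]] * t + k[["C2"]] * t^2) /
    (1 + k[["d1"]] * t + k[["d2"]] * t^2 + k[["d3"]] * t^3)
}

#' 1955 rational quantile approximations
#'
#' The first published rational approximations to the normal quantile:
#' a four-constant form
#' \eqn{X^*(q) = \eta - (\alpha_0+\alpha_1\eta)/(1+b_1\eta+b_2\eta^2)} and a
#' six-constant form whose constants are identical to those of
#' [inverseNormalRational()], with \eqn{\eta = \sqrt{\ln(1/q^2)}}.
#'
#' @param q upper-tail probability in (0, 0.5]; vectorised.
#' @param constants constant list as from [normalApproxConstants()].
#' @param variant `"6-constant"` (default) or `"4-constant"`.
#' @export
hastingsInverse <- function(q, constants = normalApproxConstants(),
                            variant = c("6-constant", "4-constant")) {
  variant <- match.arg(variant)
  eta <- .tailTransform(q, "q")
  if (variant == "4-constant") {
    k <- constants$hastings4
    eta - (k[["a0"]] + k[["a1"]] * eta) /
      (1 + k[["b1"]] * eta + k[["b2"]] * eta^2)
  } else {
    k <- constants$hastings6
    eta - (k[["a0"]] + k[["a1"]] * eta + k[["a2"]] * eta^2) /
      (1 + k[["b1"]] * eta + k[["b2"]] * eta^2 + k[["b3"]] * eta^3)
  }
}

#' Composite-exponential approximation to \eqn{\Phi(z) - 0.5}
#'
#' For \eqn{z \ge 0}:
#' \deqn{\Phi(z)-0.5 \approx 0.5\sqrt{1 - \tfrac{1}{30}\left[7e^{-z^2/2} +
#'   16e^{-z^2(2-\sqrt 2)} + (7 + \tfrac{\pi z^2}{4})e^{-z^2}\right]}}
#' The bracket sums to exactly 30 at z = 0, so the approximation is 0 there and
#' rises to 0.5 as \eqn{z \to \infty}. Its measured maximum absolute error on
#' [0, 10] is 3.04e-5 (near z = 0.40). Callers needing negative z use the
#' symmetry \eqn{\Phi(-z) = 1 - \Phi(z)}.
#'
#' @param z nonnegative numeric vector.
#' @export
cdfCompositeExponential <- function(z) {
  .checkFinite(z, "z")
  if (any(z < 0))
    stop("'z' must be >= 0; use symmetry for the lower half", call. = FALSE)
  bracket <- 7 * exp(-z^2 / 2) +
    16 * exp(-z^2 * (2 - sqrt(2))) +
    (7 + pi * z^2 / 4) * exp(-z^2)
  0.5 * sqrt(pmax(1 - bracket / 30, 0))
}

#' Error scan of an approximation against its oracle
#'
#' Evaluates `approxFn` and `oracleFn` on the grid
#' `seq(gridLo, gridHi, by = gridStep)` and records the maximum absolute
#' deviation and where it occurs.
#'
#' @param approxFn,oracleFn vectorised functions of one numeric argument.
#' @param gridLo,gridHi grid endpoints, `gridLo < gridHi`.
#' @param gridStep positive grid spacing.
#' @return an [ErrorScanReport-class] object.
#' @examples
#' errorScan(cdfCompositeExponential, function(z) exactNormalCdf(z) - 0.5, 0, 10, 1e-3)
#' @export
errorScan <- function(approxFn, oracleFn, gridLo, gridHi, gridStep) {
  if (!is.finite(gridLo) || !is.finite(gridHi) || gridLo >= gridHi)
    stop("need gridLo < gridHi, both finite", call. = FALSE)
  if (!is.finite(gridStep) || gridStep <= 0)
    stop("'gridStep' must be positive", call. = FALSE)
  grid <- seq(gridLo, gridHi, by = gridStep)
  if (length(grid) == 0L) stop("empty scan grid", call. = FALSE)
  err <- abs(approxFn(grid) - oracleFn(grid))
  i <- which.max(err)
  new("ErrorScanReport", gridLo = gridLo, gridHi = gridHi, gridStep = gridStep,
      maxAbsError = err[i], argmax = grid[i])
}

#' Error-scan report
#'
#' Result of [errorScan()]: the scanned interval, the maximum absolute error
#' between approximation and oracle, and the grid point attaining it.
#'
#' @slot gridLo,gridHi,gridStep scan grid definition.
#' @slot maxAbsError maximum absolute deviation over the grid.
#' @slot argmax grid point where the maximum occurs.
#' @export
setClass("ErrorScanReport",
         representation(gridLo = "numeric", gridHi = "numeric",
                        gridStep = "numeric", maxAbsError = "numeric",
                        argmax = "numeric"),
         validity = function(object) {
           if (object@maxAbsError < 0) return("maxAbsError must be >= 0")
           if (object@gridLo >= object@gridHi) return("gridLo must be < gridHi")
           if (object@argmax < object@gridLo || object@argmax > object@gridHi)
             return("argmax outside scan interval")
           TRUE
         })

#' @describeIn ErrorScanReport-class compact display.
#' @param object an `ErrorScanReport`.
#' @export
setMethod("show", "ErrorScanReport", function(object) {
  cat(sprintf("ErrorScanReport on [%g, %g] (step %g)\n  max |error| = %.6g at %g\n",
              object@gridLo, object@gridHi, object@gridStep,
              object@maxAbsError, object@argmax))
})

#' @describeIn ErrorScanReport-class maximum absolute error.
#' @export
maxAbsError <- function(object) object@maxAbsError
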