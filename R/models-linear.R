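#' Numerically stable sigmoid
#'
#' `1 / (1 + exp(-u))`, evaluated so that neither tail overflows for |u| up
#' to the double range; output is strictly inside (0, 1).
#'
#' @param u numeric vector or matrix.
#' @return values of the logistic function, same shape as `u`.
#' @export
sigmoid <- function(u) {
  out <- stats::plogis(u)     # C implementation of 1 / (1 + exp(-u))
  if (is.matrix(u)) dim(out) <- dim(u)
  out
}

## logit of a rate clamped away from {0, 1}; used to bias sigmoid outputs
## toward the training-target mean at initialization
.logit <- function(p, eps = 1e-9) {
  p <- pmin(1 - eps, pmax(eps, p))
  log(p / (1 - p))
}

#' Fit multiple linear regression by penalized least squares
#'
#' Minimizes the training RMSE of `y ~ a0 + a . x`. A tiny ridge penalty
#' (default 1e-8) keeps the normal equations well-posed when the feature
#' count exceeds the sample count — the standard situation for contaminant
#' indicator tables — and selects the minimum-norm solution among the
#' least-squares minimizers. When n > N the dual (Gram-matrix) form is
#' solved instead of the n x n system.
#'
#' @param x numeric matrix, tuples x features, fully imputed.
#' @param y numeric morbidity targets.
#' @param ridge ridge coefficient.
#' @return an [MLRModel-class].
#' @export
mlrFit <- function(x, y, ridge = 1e-8) {
  x <- as.matrix(x)
  stopIfNot(ncol(x) >= 1L, "need at least one feature")
  stopIfNot(nrow(x) == length(y), "x rows must match length(y)")
  stopIfNot(!anyNA(x), "features must be imputed before fitting")
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2L, xm, "-"); yc <- y - ym
  n <- ncol(x); N <- nrow(x)
  a <- if (N >= n) {
    as.numeric(solve(crossprod(xc) + diag(ridge, n), crossprod(xc, yc)))
  } else {
    alpha <- solve(tcrossprod(xc) + diag(ridge, N), yc)
    as.numeric(crossprod(xc, alpha))
  }
  new("MLRModel", intercept = ym - sum(a * xm), coefficients = a)
}

#' @describeIn mlrFit raw (unclipped) linear prediction `a0 + a . x`.
#' @param model an [MLRModel-class].
#' @export
mlrPredict <- function(model, x) {
  x <- .rowmat(x)
  as.numeric(x %*% model@coefficients + model@intercept)
}

#' @rdname predictMorbidity
#' @export
setMethod("predictMorbidity", "MLRModel", function(object, x, ...) {
  pmin(1, pmax(0, mlrPredict(object, x)))
})

setMethod("show", "MLRModel", function(object) {
  cat("MLRModel:", length(object@coefficients), "coefficients, intercept",
      signif(object@intercept, 6), "\n")
})

#' @rdname nParams
#' @export
setMethod("nParams", "MLRModel",
          function(object) length(object@coefficients) + 1L)
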