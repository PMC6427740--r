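#' Construct a randomly initialized shallow network
#'
#' Hidden width defaults to `round(sqrt(n))`: a hidden layer as wide as the
#' input is impractical at tens of thousands of indicators, and the square
#' root keeps capacity growing sublinearly with dimension (configurable).
#' The output threshold is initialized at `-logit(yMean)` so the network
#' starts predicting near the target mean, which matters when morbidity is
#' of order 1e-4 and the sigmoid output would otherwise sit at 0.5.
#'
#' @param n input dimension.
#' @param m hidden width (default `round(sqrt(n))`, at least 2).
#' @param seed integer seed.
#' @param yMean target mean used to bias the output unit.
#' @param initSd sd of the random weight initialization.
#' @return a [ShallowANN-class].
#' @export
shallowANN <- function(n, m = max(2L, round(sqrt(n))), seed = 1L,
                       yMean = 0.5, initSd = 0.1) {
  withSeed(seed, {
    new("ShallowANN",
        wIn = matrix(rnorm(n * m, 0, initSd), n, m),
        thetaHidden = rnorm(m, 0, initSd),
        wOut = rnorm(m, 0, initSd),
        thetaOut = -.logit(yMean))
  })
}

#' Forward pass of the shallow network
#'
#' Hidden unit j computes `z_j = s(sum_i w_ij x_i - theta_j)`; the output
#' unit computes `y = s(sum_j w_j z_j - theta_0)`.
#'
#' @param model a [ShallowANN-class].
#' @param x numeric vector of length n or matrix (rows = tuples).
#' @return numeric predictions in (0, 1).
#' @export
annForward <- function(model, x) {
  x <- .rowmat(x)
  stopIfNot(ncol(x) == nrow(model@wIn),
            "input dimension does not match the network")
  z <- sigmoid(sweep(x %*% model@wIn, 2L, model@thetaHidden, "-"))
  as.numeric(sigmoid(z %*% model@wOut - model@thetaOut))
}

#' @rdname predictMorbidity
#' @export
setMethod("predictMorbidity", "ShallowANN", function(object, x, ...) {
  annForward(object, x)       # sigmoid output is already inside (0, 1)
})

## per-sample squared-error gradient of the shallow network; returns the
## same slots as the model. Shared by training and the finite-difference
## tests.
annGradient <- function(model, x, target) {
  z <- as.numeric(sigmoid(x %*% model@wIn - model@thetaHidden))
  o <- as.numeric(sigmoid(sum(model@wOut * z) - model@thetaOut))
  dOut <- 2 * (o - target) * o * (1 - o)
  dHid <- dOut * model@wOut * z * (1 - z)
  list(wIn = outer(as.numeric(x), dHid), thetaHidden = -dHid,
       wOut = dOut * z, thetaOut = -dOut)
}

#' Train the shallow network by stochastic back-propagation
#'
#' Per-sample stochastic gradient descent on the squared prediction error,
#' visiting the training pairs in a reshuffled order each epoch; the
#' epoch-best parameters by training RMSE are returned. Deterministic for a
#' fixed seed.
#'
#' @param x numeric matrix, tuples x features (imputed, standardized).
#' @param y morbidity targets in `[0, 1]`.
#' @param m hidden width.
#' @param epochs full passes over the data.
#' @param lr learning rate.
#' @param seed integer seed.
#' @return a [ShallowANN-class] (best epoch snapshot); attribute
#'   `"rmseHistory"` records the per-epoch training RMSE.
#' @export
annTrainBackprop <- function(x, y, m = max(2L, round(sqrt(ncol(x)))),
                             epochs = 30L, lr = 0.1, seed = 1L) {
  x <- as.matrix(x)
  stopIfNot(nrow(x) == length(y) && nrow(x) > 0, "need non-empty pairs")
  model <- shallowANN(ncol(x), m, seed = subSeed(seed, 1L), yMean = mean(y))
  best <- model
  bestRmse <- rmse(annForward(model, x), y)
  hist <- numeric(epochs)
  withSeed(subSeed(seed, 2L), {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(nrow(x))) {
        g <- annGradient(model, x[i, , drop = FALSE], y[i])
        if (!all(is.finite(g$wIn))) stop("non-finite training loss gradient")
        model@wIn <- model@wIn - lr * g$wIn
        model@thetaHidden <- model@thetaHidden - lr * g$thetaHidden
        model@wOut <- model@wOut - lr * g$wOut
        model@thetaOut <- model@thetaOut - lr * g$thetaOut
      }
      hist[ep] <- rmse(annForward(model, x), y)
      if (hist[ep] < bestRmse) { bestRmse <- hist[ep]; best <- model }
    }
  })
  attr(best, "rmseHistory") <- hist
  best
}

setMethod("show", "ShallowANN", function(object) {
  cat("ShallowANN:", nrow(object@wIn), "->", ncol(object@wIn), "-> 1",
      "(sigmoid units)\n")
})

#' @rdname nParams
#' @export
setMethod("nParams", "ShallowANN", function(object) {
  length(object@wIn) + length(object@thetaHidden) + length(object@wOut) + 1L
})
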