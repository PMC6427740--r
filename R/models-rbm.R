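#' Construct a restricted Boltzmann machine layer
#'
#' @param nVisible,nHidden layer sizes.
#' @param visibleKind `"gaussian"` for the bottom layer of a stack (real,
#'   standardized inputs, unit variances) or `"bernoulli"` for upper layers.
#' @param seed integer seed for the small random weight initialization.
#' @return an [RBMLayer-class].
#' @export
rbmLayer <- function(nVisible, nHidden, visibleKind = "bernoulli", seed = 1L) {
  withSeed(seed, {
    new("RBMLayer", w = matrix(rnorm(nVisible * nHidden, 0, 0.05),
                               nVisible, nHidden),
        b = numeric(nVisible), c = numeric(nHidden),
        visibleKind = visibleKind)
  })
}

#' RBM energy of a (visible, hidden) configuration
#'
#' Bernoulli visible units: `E = -b'x - c'z - x'Wz`. Gaussian visible units
#' (unit variance, appropriate for standardized real inputs):
#' `E = sum((x - b)^2) / 2 - c'z - x'Wz`.
#'
#' @param layer an [RBMLayer-class].
#' @param x visible vector; `z` binary hidden vector.
#' @return numeric(1) energy.
#' @export
rbmEnergy <- function(layer, x, z) {
  interact <- as.numeric(t(x) %*% layer@w %*% z)
  if (layer@visibleKind == "gaussian") {
    sum((x - layer@b)^2) / 2 - sum(layer@c * z) - interact
  } else {
    -sum(layer@b * x) - sum(layer@c * z) - interact
  }
}

#' @rdname rbmEnergy
#' @param z binary hidden vector.
NULL

## hidden activation probabilities, rows = samples
rbmHiddenProb <- function(layer, X)
  sigmoid(.addCols(X %*% layer@w, layer@c))

## deterministic (mean-field) one-step reconstruction from hidden activity
rbmReconstructDet <- function(layer, H) {
  lin <- .addCols(tcrossprod(H, layer@w), layer@b)
  if (layer@visibleKind == "gaussian") lin else sigmoid(lin)
}

#' Deterministic one-step reconstruction error
#'
#' Mean over the batch of the squared Euclidean distance between the input
#' and its mean-field reconstruction through the hidden layer. This is the
#' tractable fitness used by evolutionary pretraining (the exact RBM
#' log-likelihood requires the partition function), and the monitoring
#' quantity of contrastive-divergence training.
#'
#' @param layer an [RBMLayer-class].
#' @param X numeric matrix, samples x visible.
#' @return numeric(1).
#' @export
rbmReconError <- function(layer, X) {
  X <- .rowmat(X)
  R <- rbmReconstructDet(layer, rbmHiddenProb(layer, X))
  mean(rowSums((X - R)^2))
}

#' One step of contrastive divergence (CD-1)
#'
#' Samples hidden units given the visible batch, reconstructs the visible
#' layer (mean-field), recomputes hidden probabilities, and applies the CD-1
#' gradient `W += lr (<x h>_data - <x h>_recon)` (similarly for both bias
#' vectors), averaged over the batch. Randomness (the hidden sampling) comes
#' from the current RNG state; seed with [withSeed()] or a caller seed for
#' reproducibility.
#'
#' @param layer an [RBMLayer-class].
#' @param X batch matrix, samples x visible (standardized for gaussian
#'   layers, in `[0, 1]` for bernoulli layers).
#' @param lr learning rate.
#' @return list: `layer` (updated), `reconError` (deterministic one-step
#'   reconstruction error of the *input* layer, reported before the update).
#' @export
rbmCDStep <- function(layer, X, lr) {
  X <- .rowmat(X)
  N <- nrow(X)
  errBefore <- rbmReconError(layer, X)
  h0p <- rbmHiddenProb(layer, X)
  h0 <- matrix(as.numeric(runif(length(h0p)) < h0p), nrow(h0p), ncol(h0p))
  v1 <- rbmReconstructDet(layer, h0)
  h1p <- rbmHiddenProb(layer, v1)
  dW <- (crossprod(X, h0p) - crossprod(v1, h1p)) / N
  db <- colMeans(X) - colMeans(v1)
  dc <- colMeans(h0p) - colMeans(h1p)
  layer@w <- layer@w + lr * dW
  layer@b <- layer@b + lr * db
  layer@c <- layer@c + lr * dc
  list(layer = layer, reconError = errBefore)
}

setMethod("show", "RBMLayer", function(object) {
  cat("RBMLayer:", nrow(object@w), "visible (", object@visibleKind, ") x",
      ncol(object@w), "hidden\n")
})
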