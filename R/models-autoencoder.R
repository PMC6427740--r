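#' Construct a (denoising) autoencoder layer
#'
#' @param nVisible,nHidden layer sizes.
#' @param rho masking corruption rate in `[0, 1)`; 0 gives a plain
#'   autoencoder.
#' @param seed integer seed for the random weight initialization.
#' @return an [AutoencoderLayer-class].
#' @export
autoencoderLayer <- function(nVisible, nHidden, rho = 0, seed = 1L) {
  withSeed(seed, {
    new("AutoencoderLayer",
        w = matrix(rnorm(nHidden * nVisible, 0, 0.05), nHidden, nVisible),
        b = numeric(nHidden),
        wp = matrix(rnorm(nVisible * nHidden, 0, 0.05), nVisible, nHidden),
        bp = numeric(nVisible), rho = rho)
  })
}

#' Autoencoder affine-sigmoid mappings
#'
#' Encode: `z = s(w x + b)`; decode: `x' = s(w' z + b')`.
#'
#' @param layer an [AutoencoderLayer-class].
#' @param x visible vector or matrix (rows = samples); `z` hidden likewise.
#' @return encoded / decoded matrix with one row per sample (a vector input
#'   gives a one-row matrix).
#' @export
aeEncode <- function(layer, x) {
  x <- .rowmat(x)
  stopIfNot(ncol(x) == ncol(layer@w), "visible dimension mismatch")
  sigmoid(.addCols(tcrossprod(x, layer@w), layer@b))
}

#' @rdname aeEncode
#' @param z hidden vector or matrix.
#' @export
aeDecode <- function(layer, z) {
  z <- .rowmat(z)
  stopIfNot(ncol(z) == ncol(layer@wp), "hidden dimension mismatch")
  sigmoid(.addCols(tcrossprod(z, layer@wp), layer@bp))
}

#' Masking corruption
#'
#' Independently zeroes each component with probability `rho` (masking
#' noise, the canonical corruption of the denoising-autoencoder lineage;
#' Gaussian-additive corruption is available via `kind = "gaussian"`). With
#' `rho = 0` the input is returned untouched and no random numbers are
#' consumed, so a denoising stack at rate 0 follows the exact RNG stream of
#' a plain stack.
#'
#' @param x numeric vector or matrix (rows = samples).
#' @param rho corruption rate in `[0, 1)`.
#' @param kind `"mask"` (zeroing) or `"gaussian"` (additive N(0, rho)).
#' @param mask optional logical testing hook marking the entries to corrupt.
#' @return corrupted copy of `x`.
#' @export
corruptInput <- function(x, rho, kind = c("mask", "gaussian"), mask = NULL) {
  kind <- match.arg(kind)
  stopIfNot(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  if (rho == 0 && is.null(mask)) return(x)
  if (kind == "gaussian")
    return(x + rnorm(length(x), 0, rho))
  if (is.null(mask)) mask <- runif(length(x)) < rho
  x[mask] <- 0
  x
}

#' Mean reconstruction loss of an autoencoder layer
#'
#' Mean over the batch of `||x - x'||^2` where `x'` is the reconstruction of
#' the (optionally corrupted) input; the comparison is always against the
#' clean `x`, which is what makes the denoising variant learn to repair its
#' input rather than copy it.
#'
#' @param layer an [AutoencoderLayer-class].
#' @param X clean batch, samples x visible.
#' @param Xcorrupt optional corrupted batch actually fed to the encoder
#'   (defaults to `X`).
#' @return numeric(1).
#' @export
aeReconstructionLoss <- function(layer, X, Xcorrupt = NULL) {
  X <- .rowmat(X)
  stopIfNot(nrow(X) > 0, "batch must be non-empty")
  if (is.null(Xcorrupt)) Xcorrupt <- X
  R <- aeDecode(layer, aeEncode(layer, Xcorrupt))
  mean(rowSums((X - R)^2))
}

## batch gradient of the reconstruction loss wrt (w, b, wp, bp);
## shared by gradient pretraining and the finite-difference tests
aeGradient <- function(layer, X, Xcorrupt = NULL) {
  X <- .rowmat(X)
  if (is.null(Xcorrupt)) Xcorrupt <- X
  N <- nrow(X)
  Z <- aeEncode(layer, Xcorrupt)
  R <- aeDecode(layer, Z)
  dOut <- 2 * (R - X) * R * (1 - R) / N            # N x visible
  dHid <- (dOut %*% layer@wp) * Z * (1 - Z)        # N x hidden
  list(w = crossprod(dHid, Xcorrupt), b = colSums(dHid),
       wp = crossprod(dOut, Z), bp = colSums(dOut))
}

#' One batch gradient-descent step on the reconstruction loss
#'
#' @param layer an [AutoencoderLayer-class].
#' @param X clean batch; corruption at the layer's `rho` is drawn from the
#'   current RNG state.
#' @param lr learning rate.
#' @return list: `layer` (updated), `loss` (reconstruction loss before the
#'   update, against clean inputs).
#' @export
aeGradStep <- function(layer, X, lr) {
  X <- .rowmat(X)
  Xc <- corruptInput(X, layer@rho)
  loss <- aeReconstructionLoss(layer, X, Xc)
  g <- aeGradient(layer, X, Xc)
  layer@w <- layer@w - lr * g$w
  layer@b <- layer@b - lr * g$b
  layer@wp <- layer@wp - lr * g$wp
  layer@bp <- layer@bp - lr * g$bp
  list(layer = layer, loss = loss)
}

setMethod("show", "AutoencoderLayer", function(object) {
  cat("AutoencoderLayer:", ncol(object@w), "visible <->", nrow(object@w),
      "hidden; corruption rho =", object@rho, "\n")
})
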