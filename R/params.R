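#' Construct a deep stack of RBM or autoencoder layers
#'
#' `kind = "DBN"` builds RBM layers (gaussian-visible bottom, bernoulli
#' above); `"DAE"`/`"DDAE"` build autoencoder layers (corruption `rho`
#' applies only to the DDAE). Layer sizes chain from `inputDim` through
#' `hiddenSizes`.
#'
#' @param kind `"DBN"`, `"DAE"` or `"DDAE"`.
#' @param inputDim feature count n.
#' @param hiddenSizes integer hidden widths, outermost first.
#' @param rho corruption rate for DDAE layers.
#' @param seed integer seed for the layer initializations.
#' @return a [DeepStack-class].
#' @export
deepStack <- function(kind, inputDim, hiddenSizes, rho = 0.2, seed = 1L) {
  kind <- match.arg(kind, c("DBN", "DAE", "DDAE"))
  hiddenSizes <- as.integer(hiddenSizes)
  sizes <- c(as.integer(inputDim), hiddenSizes)
  layers <- lapply(seq_along(hiddenSizes), function(i) {
    s <- subSeed(seed, i)
    if (kind == "DBN") {
      rbmLayer(sizes[i], sizes[i + 1L],
               visibleKind = if (i == 1L) "gaussian" else "bernoulli",
               seed = s)
    } else {
      autoencoderLayer(sizes[i], sizes[i + 1L],
                       rho = if (kind == "DDAE") rho else 0, seed = s)
    }
  })
  new("DeepStack", kind = kind, layers = layers, hiddenSizes = hiddenSizes,
      inputDim = as.integer(inputDim))
}

setMethod("show", "DeepStack", function(object) {
  cat("DeepStack (", object@kind, "): ", object@inputDim, " -> ",
      paste(object@hiddenSizes, collapse = " -> "), "\n", sep = "")
})

## deterministic encoder pass of a single layer, rows = samples
layerEncode <- function(layer, X) {
  if (is(layer, "RBMLayer")) rbmHiddenProb(layer, X) else aeEncode(layer, X)
}

#' Encode a batch through the whole stack
#'
#' Deterministic forward pass: each layer's sigmoid activation feeds the
#' next, so the result is the top-layer code matrix used by the mixture
#' output head.
#'
#' @param stack a [DeepStack-class].
#' @param X numeric matrix, samples x inputDim.
#' @return numeric matrix, samples x top hidden width.
#' @export
stackEncode <- function(stack, X) {
  X <- .rowmat(X)
  for (layer in stack@layers) X <- layerEncode(layer, X)
  X
}

## ---- flat parameter codecs ---------------------------------------------
## Order conventions (column-major within each matrix):
##   ShallowANN:        wIn, thetaHidden, wOut, thetaOut
##   RBMLayer:          b, c, w
##   AutoencoderLayer:  w, b, wp, bp
##   DeepStack:         layers in order

#' @rdname nParams
#' @export
setMethod("nParams", "RBMLayer", function(object)
  length(object@b) + length(object@c) + length(object@w))

#' @rdname nParams
#' @export
setMethod("nParams", "AutoencoderLayer", function(object)
  length(object@w) + length(object@b) + length(object@wp) + length(object@bp))

#' @rdname nParams
#' @export
setMethod("nParams", "DeepStack", function(object)
  sum(vapply(object@layers, nParams, 0L)))

#' @rdname flattenParams
#' @export
setMethod("flattenParams", "ShallowANN", function(object)
  c(as.numeric(object@wIn), object@thetaHidden, object@wOut, object@thetaOut))

#' @rdname flattenParams
#' @export
setMethod("restoreParams", "ShallowANN", function(object, values) {
  stopIfNot(length(values) == nParams(object), "parameter length mismatch")
  n <- nrow(object@wIn); m <- ncol(object@wIn)
  object@wIn <- matrix(values[seq_len(n * m)], n, m)
  object@thetaHidden <- values[n * m + seq_len(m)]
  object@wOut <- values[n * m + m + seq_len(m)]
  object@thetaOut <- values[n * m + 2L * m + 1L]
  object
})

#' @rdname flattenParams
#' @export
setMethod("flattenParams", "RBMLayer", function(object)
  c(object@b, object@c, as.numeric(object@w)))

#' @rdname flattenParams
#' @export
setMethod("restoreParams", "RBMLayer", function(object, values) {
  stopIfNot(length(values) == nParams(object), "parameter length mismatch")
  nv <- length(object@b); nh <- length(object@c)
  object@b <- values[seq_len(nv)]
  object@c <- values[nv + seq_len(nh)]
  object@w <- matrix(values[nv + nh + seq_len(nv * nh)], nv, nh)
  object
})

#' @rdname flattenParams
#' @export
setMethod("flattenParams", "AutoencoderLayer", function(object)
  c(as.numeric(object@w), object@b, as.numeric(object@wp), object@bp))

#' @rdname flattenParams
#' @export
setMethod("restoreParams", "AutoencoderLayer", function(object, values) {
  stopIfNot(length(values) == nParams(object), "parameter length mismatch")
  nh <- nrow(object@w); nv <- ncol(object@w)
  object@w <- matrix(values[seq_len(nh * nv)], nh, nv)
  object@b <- values[nh * nv + seq_len(nh)]
  object@wp <- matrix(values[nh * nv + nh + seq_len(nv * nh)], nv, nh)
  object@bp <- values[2L * nh * nv + nh + seq_len(nv)]
  object
})

#' @rdname flattenParams
#' @export
setMethod("flattenParams", "DeepStack", function(object)
  unlist(lapply(object@layers, flattenParams), use.names = FALSE))

#' @rdname flattenParams
#' @export
setMethod("restoreParams", "DeepStack", function(object, values) {
  stopIfNot(length(values) == nParams(object), "parameter length mismatch")
  off <- 0L
  for (i in seq_along(object@layers)) {
    np <- nParams(object@layers[[i]])
    object@layers[[i]] <- restoreParams(object@layers[[i]],
                                        values[off + seq_len(np)])
    off <- off + np
  }
  object
})

## ---- encoder-only codec -------------------------------------------------
## Fine-tuning optimizes the parameters that influence predictions: each
## layer's encoding weights and hidden biases (RBM decoder biases and AE
## decoder weights do not enter the forward pass).

## list of (W, b) with H = s(X %*% W + b) per layer
encoderPieces <- function(stack) {
  lapply(stack@layers, function(ly) {
    if (is(ly, "RBMLayer")) list(W = ly@w, b = ly@c)
    else list(W = t(ly@w), b = ly@b)
  })
}

encoderParamCount <- function(stack)
  sum(vapply(encoderPieces(stack), function(p) length(p$W) + length(p$b), 0L))

encoderParams <- function(stack)
  unlist(lapply(encoderPieces(stack),
                function(p) c(as.numeric(p$W), p$b)), use.names = FALSE)

setEncoderParams <- function(stack, values) {
  off <- 0L
  for (i in seq_along(stack@layers)) {
    ly <- stack@layers[[i]]
    if (is(ly, "RBMLayer")) {
      nw <- length(ly@w); nb <- length(ly@c)
      ly@w <- matrix(values[off + seq_len(nw)], nrow(ly@w), ncol(ly@w))
      ly@c <- values[off + nw + seq_len(nb)]
    } else {
      nw <- length(ly@w); nb <- length(ly@b)
      Wt <- matrix(values[off + seq_len(nw)], ncol(ly@w), nrow(ly@w))
      ly@w <- t(Wt)
      ly@b <- values[off + nw + seq_len(nb)]
    }
    off <- off + nw + nb
    stack@layers[[i]] <- ly
  }
  stopIfNot(off == length(values), "encoder parameter length mismatch")
  stack
}
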