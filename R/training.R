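#' Training specification for the eight model kinds
#'
#' One object collecting the knobs of every training regime; each model kind
#' reads the subset it needs. Deep-stack defaults are the test-scale widths
#' 60/24/8/4; at 5,000+ features the full-scale widths (DBN 3860/550/80/12,
#' DAE/DDAE 4500/640/80/12) are used instead.
#'
#' @param modelKind one of `"MLR"`, `"ANN"`, `"DBN"`, `"EvoDBN"`, `"DAE"`,
#'   `"EvoDAE"`, `"DDAE"`, `"EvoDDAE"`.
#' @param hiddenSizes deep-stack hidden widths (`NULL` = scale default).
#' @param m shallow-network hidden width (`NULL` = `round(sqrt(n))`).
#' @param epochs,lr fine-tuning gradient budget.
#' @param preEpochs,preLr layerwise pretraining gradient budget.
#' @param rho denoising corruption rate (DDAE/EvoDDAE only).
#' @param gmmK mixture components of the output head.
#' @param refreshEvery epochs between head refits during gradient
#'   fine-tuning (the head is refit once per generation during evolutionary
#'   fine-tuning).
#' @param wwoPre,wwoFine [wwoConfig()]s for evolutionary pretraining (per
#'   layer) and fine-tuning. Pretraining searches the weight box from
#'   scratch and keeps the customary initial wavelength 0.5; fine-tuning
#'   starts from a pretrained solution whose neighbourhood must be searched
#'   locally, so its default initial wavelength is 0.001 — at 0.5 the first
#'   propagation steps would span half the weight range in every one of
#'   thousands of dimensions and essentially restart the search.
#' @param weightBounds search interval per parameter for the evolutionary
#'   regime; `[-4, 4]` covers the useful sigmoid operating range after input
#'   standardization.
#' @param ridge MLR ridge coefficient.
#' @param seed integer seed.
#' @return a `TrainSpec` list.
#' @export
trainSpec <- function(modelKind = "MLR", hiddenSizes = NULL, m = NULL,
                      epochs = 30L, lr = 0.3, preEpochs = 10L, preLr = 0.1,
                      rho = 0.2, gmmK = 3L, refreshEvery = 5L,
                      wwoPre = wwoConfig(populationSize = 8L, budget = 120L),
                      wwoFine = wwoConfig(populationSize = 8L, budget = 300L,
                                          lambdaInit = 0.001),
                      weightBounds = c(-4, 4), ridge = 1e-8, seed = 1L) {
  modelKind <- match.arg(modelKind, c("MLR", "ANN", "DBN", "EvoDBN", "DAE",
                                      "EvoDAE", "DDAE", "EvoDDAE"))
  stopIfNot(length(weightBounds) == 2L && weightBounds[1] < weightBounds[2],
            "weightBounds must be a finite interval")
  structure(list(modelKind = modelKind, hiddenSizes = hiddenSizes, m = m,
                 epochs = as.integer(epochs), lr = lr,
                 preEpochs = as.integer(preEpochs), preLr = preLr, rho = rho,
                 gmmK = as.integer(gmmK),
                 refreshEvery = as.integer(refreshEvery),
                 wwoPre = wwoPre, wwoFine = wwoFine,
                 weightBounds = weightBounds, ridge = ridge,
                 seed = as.integer(seed)),
            class = "TrainSpec")
}

.defaultHidden <- function(kind, n) {
  if (n >= 5000L) {
    if (kind %in% c("DBN", "EvoDBN")) c(3860L, 550L, 80L, 12L)
    else c(4500L, 640L, 80L, 12L)
  } else c(60L, 24L, 8L, 4L)
}

.stackKind <- function(modelKind)
  switch(modelKind, DBN = , EvoDBN = "DBN", DAE = , EvoDAE = "DAE",
         DDAE = , EvoDDAE = "DDAE")

#' @rdname predictMorbidity
#' @export
setMethod("predictMorbidity", "DeepPredictor", function(object, x, ...) {
  z <- stackEncode(object@stack, x)
  pmin(1, pmax(0, gmmPredict(object@head, z)))
})

setMethod("show", "DeepPredictor", function(object) {
  cat("DeepPredictor:", object@kindLabel, "\n")
  show(object@stack)
  show(object@head)
})

## training RMSE of a stack + head on (X, y)
.stackRmse <- function(stack, head, X, y)
  rmse(pmin(1, pmax(0, gmmPredict(head, stackEncode(stack, X)))), y)

#' Greedy layerwise gradient pretraining
#'
#' Trains layer 1 on the data and each subsequent layer on the previous
#' layer's deterministic codes (RBMs by contrastive divergence, autoencoder
#' layers by full-batch gradient descent on the reconstruction loss, with
#' masking corruption for denoising layers); later layers never see raw
#' features. With zero epochs the stack is returned unchanged.
#'
#' @param stack a [DeepStack-class].
#' @param X training features (imputed, standardized), samples x inputDim.
#' @param spec a [trainSpec()].
#' @return the trained stack; attribute `"lossHistory"` is a list of
#'   per-layer loss traces.
#' @export
pretrainGradient <- function(stack, X, spec) {
  X <- .rowmat(X)
  hist <- vector("list", length(stack@layers))
  withSeed(subSeed(spec$seed, 11L), {
    input <- X
    for (i in seq_along(stack@layers)) {
      ly <- stack@layers[[i]]
      losses <- numeric(spec$preEpochs)
      for (ep in seq_len(spec$preEpochs)) {
        step <- if (is(ly, "RBMLayer")) {
          st <- rbmCDStep(ly, input, spec$preLr)
          list(layer = st$layer, loss = st$reconError)
        } else aeGradStep(ly, input, spec$preLr)
        ly <- step$layer
        losses[ep] <- step$loss
        if (!is.finite(losses[ep]))
          stop("non-finite pretraining loss in layer ", i)
      }
      stack@layers[[i]] <- ly
      hist[[i]] <- losses
      input <- layerEncode(ly, input)
    }
  })
  attr(stack, "lossHistory") <- hist
  stack
}

## one full-batch gradient-descent step on the mean squared prediction
## error with a frozen head; returns the updated encoder parameter vector
finetuneStepOnce <- function(stack, head, X, y, lr) {
  acts <- vector("list", length(stack@layers) + 1L)
  acts[[1L]] <- X
  for (i in seq_along(stack@layers))
    acts[[i + 1L]] <- layerEncode(stack@layers[[i]], acts[[i]])
  Z <- acts[[length(acts)]]
  pred <- gmmPredict(head, Z)
  N <- nrow(X)
  delta <- 2 * (pred - y) / N * .gmmGradBatch(head, Z)
  if (!all(is.finite(delta))) stop("non-finite fine-tuning gradient")
  pieces <- encoderPieces(stack)
  for (l in rev(seq_along(pieces))) {
    A <- acts[[l + 1L]]
    D <- delta * A * (1 - A)
    gW <- crossprod(acts[[l]], D)
    gb <- colSums(D)
    if (l > 1L) delta <- D %*% t(pieces[[l]]$W)
    pieces[[l]]$W <- pieces[[l]]$W - lr * gW
    pieces[[l]]$b <- pieces[[l]]$b - lr * gb
  }
  unlist(lapply(pieces, function(p) c(as.numeric(p$W), p$b)),
         use.names = FALSE)
}

#' Gradient fine-tuning of a pretrained stack with mixture head
#'
#' Fits the Gaussian-mixture head on the top codes, then runs full-batch
#' gradient descent on the mean squared prediction error through the encoder
#' layers, back-propagating the analytic gradient of the mixture conditional
#' mean. The head is refit every `refreshEvery` epochs on the current codes.
#' Returns the training-RMSE-best snapshot, which is never worse than the
#' pretrained-only model.
#'
#' @param stack a pretrained [DeepStack-class].
#' @param X,y training pairs (standardized features, morbidity targets).
#' @param spec a [trainSpec()].
#' @return a [DeepPredictor-class]; attributes `"rmseHistory"` and
#'   `"pretrainRmse"`.
#' @export
finetuneGradient <- function(stack, X, y, spec) {
  X <- .rowmat(X)
  head <- gmmFitJoint(stackEncode(stack, X), y, K = spec$gmmK,
                      seed = subSeed(spec$seed, 21L))
  bestStack <- stack; bestHead <- head
  bestRmse <- .stackRmse(stack, head, X, y)
  pretrainRmse <- bestRmse
  hist <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    if (ep > 1L && (ep - 1L) %% spec$refreshEvery == 0L)
      head <- gmmFitJoint(stackEncode(stack, X), y, K = spec$gmmK,
                          seed = subSeed(spec$seed, 21L))
    stack <- setEncoderParams(stack,
                              finetuneStepOnce(stack, head, X, y, spec$lr))
    hist[ep] <- .stackRmse(stack, head, X, y)
    if (!is.finite(hist[ep])) stop("non-finite fine-tuning loss")
    if (hist[ep] < bestRmse) {
      bestRmse <- hist[ep]; bestStack <- stack; bestHead <- head
    }
  }
  out <- new("DeepPredictor", stack = bestStack, head = bestHead,
             kindLabel = stack@kind)
  attr(out, "rmseHistory") <- hist
  attr(out, "pretrainRmse") <- pretrainRmse
  attr(out, "trainRmse") <- bestRmse
  out
}

#' Evolutionary layerwise pretraining
#'
#' For each layer in order, runs water wave optimization over the layer's
#' flattened parameters with fitness equal to the negative deterministic
#' reconstruction error of that layer (for denoising layers, the corruption
#' mask is drawn once per layer so candidate fitnesses are comparable); the
#' optimized layer's codes then feed the next layer.
#'
#' @param stack a [DeepStack-class] (its current parameters are not used as
#'   search seeds; the population initializes uniformly in the weight box).
#' @param X training features.
#' @param spec a [trainSpec()].
#' @return the trained stack; attribute `"fitnessHistory"` per layer.
#' @export
pretrainEvolutionary <- function(stack, X, spec) {
  X <- .rowmat(X)
  hist <- vector("list", length(stack@layers))
  input <- X
  for (i in seq_along(stack@layers)) {
    ly <- stack@layers[[i]]
    inputLocal <- input
    corrupted <- if (is(ly, "AutoencoderLayer") && ly@rho > 0) {
      withSeed(subSeed(spec$seed, 30L + i),
               corruptInput(inputLocal, ly@rho))
    } else inputLocal
    objective <- if (is(ly, "RBMLayer")) {
      function(v) -rbmReconError(restoreParams(ly, v), inputLocal)
    } else {
      function(v) -aeReconstructionLoss(restoreParams(ly, v), inputLocal,
                                        corrupted)
    }
    D <- nParams(ly)
    res <- wwoOptimize(objective,
                       lower = rep(spec$weightBounds[1], D),
                       upper = rep(spec$weightBounds[2], D),
                       cfg = spec$wwoPre, seed = subSeed(spec$seed, 40L + i))
    stack@layers[[i]] <- ly <- restoreParams(ly, res$par)
    hist[[i]] <- res$history
    input <- layerEncode(ly, input)
  }
  attr(stack, "fitnessHistory") <- hist
  stack
}

#' Evolutionary fine-tuning of the whole encoder
#'
#' Optimizes the full flattened encoder parameter vector with water wave
#' optimization; fitness is `1 / (training RMSE + 1e-12)` under the current
#' mixture head. One initial wave is seeded from the pretrained parameters
#' so stage 2 starts from stage 1's solution, and the head is refit once per
#' generation on the best wave's codes (frozen within a generation so
#' candidate fitnesses are comparable). The returned model is the better of
#' the optimized and the pretrained-only model under their own heads, so
#' fine-tuning never degrades training fitness.
#'
#' @param stack a pretrained [DeepStack-class].
#' @param X,y training pairs.
#' @param spec a [trainSpec()].
#' @return a [DeepPredictor-class]; attributes `"pretrainRmse"` and
#'   `"trainRmse"`.
#' @export
finetuneEvolutionary <- function(stack, X, y, spec) {
  X <- .rowmat(X)
  headEnv <- new.env(parent = emptyenv())
  head0 <- gmmFitJoint(stackEncode(stack, X), y, K = spec$gmmK,
                       seed = subSeed(spec$seed, 21L))
  headEnv$head <- head0
  pretrainRmse <- .stackRmse(stack, head0, X, y)
  D <- encoderParamCount(stack)
  objective <- function(v)
    1 / (.stackRmse(setEncoderParams(stack, v), headEnv$head, X, y) + 1e-12)
  onGen <- function(bestPos) {
    z <- stackEncode(setEncoderParams(stack, bestPos), X)
    headEnv$head <- gmmFitJoint(z, y, K = spec$gmmK,
                                seed = subSeed(spec$seed, 21L))
  }
  init <- list(pmin(spec$weightBounds[2],
                    pmax(spec$weightBounds[1], encoderParams(stack))))
  res <- wwoOptimize(objective,
                     lower = rep(spec$weightBounds[1], D),
                     upper = rep(spec$weightBounds[2], D),
                     cfg = spec$wwoFine, seed = subSeed(spec$seed, 50L),
                     init = init, onGeneration = onGen)
  tuned <- setEncoderParams(stack, res$par)
  tunedHead <- gmmFitJoint(stackEncode(tuned, X), y, K = spec$gmmK,
                           seed = subSeed(spec$seed, 21L))
  tunedRmse <- .stackRmse(tuned, tunedHead, X, y)
  ## elitist final selection over full models
  if (tunedRmse <= pretrainRmse) {
    out <- new("DeepPredictor", stack = tuned, head = tunedHead,
               kindLabel = stack@kind)
    attr(out, "trainRmse") <- tunedRmse
  } else {
    out <- new("DeepPredictor", stack = stack, head = head0,
               kindLabel = stack@kind)
    attr(out, "trainRmse") <- pretrainRmse
  }
  attr(out, "pretrainRmse") <- pretrainRmse
  attr(out, "history") <- res$history
  out
}

#' Train any of the eight model kinds
#'
#' Dispatcher: MLR by penalized least squares, ANN by back-propagation,
#' DBN/DAE/DDAE by gradient layerwise pretraining plus gradient fine-tuning,
#' and the Evo variants by water-wave-optimization pretraining plus
#' fine-tuning. Every returned object answers [predictMorbidity()].
#'
#' @param kind model kind (see [trainSpec()]).
#' @param x training feature matrix (imputed, standardized) or a
#'   standardized [SupervisedPairs-class] (then `y` is taken from it).
#' @param y morbidity targets.
#' @param spec a [trainSpec()] (its `modelKind` is overridden by `kind`).
#' @return a fitted model with attributes `"trainRmse"` and, for deep kinds,
#'   `"pretrainRmse"`.
#' @export
trainModel <- function(kind, x, y = NULL, spec = trainSpec()) {
  if (is(x, "SupervisedPairs")) {
    stopIfNot(isTRUE(x@standardized),
              "pairs must be preprocessed (imputed + standardized) first")
    y <- x@y
    x <- x@features
  }
  x <- as.matrix(x)
  kind <- match.arg(kind, c("MLR", "ANN", "DBN", "EvoDBN", "DAE", "EvoDAE",
                            "DDAE", "EvoDDAE"))
  spec$modelKind <- kind
  n <- ncol(x)
  if (kind == "MLR") {
    model <- mlrFit(x, y, ridge = spec$ridge)
    attr(model, "trainRmse") <- rmse(predictMorbidity(model, x), y)
    return(model)
  }
  if (kind == "ANN") {
    m <- if (is.null(spec$m)) max(2L, round(sqrt(n))) else spec$m
    model <- annTrainBackprop(x, y, m = m, epochs = spec$epochs,
                              lr = spec$lr, seed = spec$seed)
    attr(model, "trainRmse") <- rmse(annForward(model, x), y)
    return(model)
  }
  hidden <- if (is.null(spec$hiddenSizes)) .defaultHidden(kind, n)
            else spec$hiddenSizes
  stack <- deepStack(.stackKind(kind), n, hidden, rho = spec$rho,
                     seed = subSeed(spec$seed, 3L))
  if (kind %in% c("DBN", "DAE", "DDAE")) {
    stack <- pretrainGradient(stack, x, spec)
    finetuneGradient(stack, x, y, spec)
  } else {
    stack <- pretrainEvolutionary(stack, x, spec)
    finetuneEvolutionary(stack, x, y, spec)
  }
}
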