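## Model serialization: a YAML manifest (kind, shapes, corruption, mixture
## size) plus the flat parameter vector as a little-endian double array.
## The round trip is bit-exact.

.headFlatten <- function(head) {
  c(head@weights, as.numeric(head@means), as.numeric(head@covariances))
}

.headRestore <- function(K, d, values) {
  d1 <- d + 1L
  nW <- K; nM <- K * d1
  new("GMMHead", weights = values[seq_len(nW)],
      means = matrix(values[nW + seq_len(nM)], K, d1),
      covariances = array(values[nW + nM + seq_len(d1 * d1 * K)],
                          c(d1, d1, K)),
      zDim = as.integer(d))
}

#' Serialize a fitted model to a directory
#'
#' Writes `manifest.yaml` (model kind and shape) and `params.bin` (the flat
#' parameter vector of [flattenParams()], plus the mixture-head parameters
#' for deep predictors, as little-endian doubles). [readModel()] restores
#' the model exactly.
#'
#' @param model an [MLRModel-class], [ShallowANN-class] or
#'   [DeepPredictor-class].
#' @param path directory (created if absent).
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (is(model, "MLRModel")) {
    manifest <- list(kind = "MLR", n = length(model@coefficients))
    params <- c(model@intercept, model@coefficients)
  } else if (is(model, "ShallowANN")) {
    manifest <- list(kind = "ANN", n = nrow(model@wIn), m = ncol(model@wIn))
    params <- flattenParams(model)
  } else if (is(model, "DeepPredictor")) {
    st <- model@stack
    rho <- if (is(st@layers[[1]], "AutoencoderLayer"))
      st@layers[[1]]@rho else 0
    manifest <- list(kind = st@kind, n = st@inputDim,
                     hidden_sizes = as.list(st@hiddenSizes),
                     corruption = rho,
                     gmm_components = length(model@head@weights),
                     label = model@kindLabel)
    params <- c(flattenParams(st), .headFlatten(model@head))
  } else stop("unsupported model class: ", class(model))
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))
  con <- file(file.path(path, "params.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(params), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname writeModel
#' @param path directory written by `writeModel`.
#' @return `readModel`: the restored model.
#' @export
readModel <- function(path) {
  manifest <- yaml::read_yaml(file.path(path, "manifest.yaml"))
  fBin <- file.path(path, "params.bin")
  params <- readBin(fBin, "double", n = file.size(fBin) / 8L, size = 8L,
                    endian = "little")
  if (manifest$kind == "MLR") {
    stopIfNot(length(params) == manifest$n + 1L, "parameter length mismatch")
    return(new("MLRModel", intercept = params[1], coefficients = params[-1]))
  }
  if (manifest$kind == "ANN") {
    shape <- shallowANN(manifest$n, manifest$m, seed = 1L)
    return(restoreParams(shape, params))
  }
  st <- deepStack(manifest$kind, manifest$n,
                  unlist(manifest$hidden_sizes),
                  rho = manifest$corruption, seed = 1L)
  np <- nParams(st)
  st <- restoreParams(st, params[seq_len(np)])
  d <- st@hiddenSizes[length(st@hiddenSizes)]
  head <- .headRestore(manifest$gmm_components, d, params[-seq_len(np)])
  new("DeepPredictor", stack = st, head = head,
      kindLabel = manifest$label)
}
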