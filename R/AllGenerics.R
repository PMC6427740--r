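#' @rdname ContaminantSchema-class
#' @param x a `ContaminantSchema`.
#' @export
setGeneric("foods", function(x) standardGeneric("foods"))

#' @rdname ContaminantSchema-class
#' @export
setGeneric("contaminants", function(x) standardGeneric("contaminants"))

#' @rdname ContaminantSchema-class
#' @export
setGeneric("nIndicators", function(x) standardGeneric("nIndicators"))

#' Predict morbidity from a feature matrix
#'
#' Uniform prediction contract shared by every fitted model kind: given a
#' matrix of imputed, standardized feature rows, return one morbidity value
#' per row, clipped to `[0, 1]`.
#'
#' @param object a fitted model.
#' @param x numeric matrix (rows = tuples) or a single feature vector.
#' @param ... unused.
#' @return numeric vector of predictions in `[0, 1]`.
#' @export
setGeneric("predictMorbidity",
           function(object, x, ...) standardGeneric("predictMorbidity"))

#' Number of free parameters of a model
#' @param object a model object.
#' @export
setGeneric("nParams", function(object) standardGeneric("nParams"))

#' Flatten model parameters to a vector / restore them from one
#'
#' `flattenParams` maps a model's parameters to a flat numeric vector in a
#' fixed, documented order; `restoreParams` inverts the mapping exactly.
#' The round trip is the bridge between model objects and the continuous
#' search space of the evolutionary optimizer.
#'
#' @param object a model (layer, stack, or network).
#' @param values numeric vector of length `nParams(object)`.
#' @return `flattenParams`: numeric vector; `restoreParams`: a model of the
#'   same shape carrying `values`.
#' @export
setGeneric("flattenParams", function(object) standardGeneric("flattenParams"))

#' @rdname flattenParams
#' @export
setGeneric("restoreParams",
           function(object, values) standardGeneric("restoreParams"))
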