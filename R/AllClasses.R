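#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats rnorm runif rbinom sd var kmeans dnorm plogis predict setNames
#' @importFrom utils read.delim read.csv write.csv head tail
#' @importFrom graphics plot abline barplot
NULL

#' Contaminant-indicator schema
#'
#' Immutable bijection between (food, contaminant) pairs and feature-column
#' ids. Column ids run 1..n with n = |foods| * |contaminants|, ordered
#' food-major: column of (food i, contaminant j) is (i-1)*|contaminants| + j.
#'
#' @slot foods character vector of unique food names.
#' @slot contaminants character vector of unique contaminant names.
#' @export
setClass("ContaminantSchema",
  representation(foods = "character", contaminants = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@foods) == 0L || length(object@contaminants) == 0L)
      msg <- c(msg, "foods and contaminants must be non-empty")
    if (anyDuplicated(object@foods))
      msg <- c(msg, "food names must be unique")
    if (anyDuplicated(object@contaminants))
      msg <- c(msg, "contaminant names must be unique")
    if (is.null(msg)) TRUE else msg
  })

#' Region-week surveillance container
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are contaminant
#' indicators (one per (food, contaminant) pair) and whose columns are
#' region-week tuples. Assay `"values"` holds the mean weekly measurement per
#' cell (NA where unmeasured) and assay `"observed"` the logical missingness
#' mask. Column metadata carries region id, week index (0-based from the
#' first study week), resident population, and per-disease incidence counts;
#' morbidity (incidence / population) is derived on demand. The schema and
#' disease list live in `metadata()`.
#'
#' @export
setClass("SurveillanceExperiment", contains = "SummarizedExperiment")

#' Time-lagged supervised pairs
#'
#' Feature vectors at week t - lag paired with one disease's morbidity at
#' week t, never crossing regions. Produced raw (with missingness mask);
#' imputation and standardization are applied per cross-validation fold so
#' training statistics never leak from test tuples.
#'
#' @slot features numeric matrix, pairs x n (NA where unobserved).
#' @slot observed logical matrix, same shape.
#' @slot y numeric morbidity targets in `[0, 1]`.
#' @slot regionId character region of each pair.
#' @slot targetWeek integer week of the target morbidity.
#' @slot disease character(1) disease label.
#' @slot lag integer(1) lag in weeks.
#' @slot standardized logical(1) whether features are imputed + z-scored.
#' @export
setClass("SupervisedPairs",
  representation(features = "matrix", observed = "matrix", y = "numeric",
                 regionId = "character", targetWeek = "integer",
                 disease = "character", lag = "integer",
                 standardized = "logical"),
  validity = function(object) {
    msg <- NULL
    n <- nrow(object@features)
    if (!all(dim(object@features) == dim(object@observed)))
      msg <- c(msg, "features and observed must have identical shape")
    if (length(object@y) != n || length(object@regionId) != n ||
        length(object@targetWeek) != n)
      msg <- c(msg, "per-pair vectors must match the number of rows")
    if (any(object@y < 0 | object@y > 1, na.rm = TRUE))
      msg <- c(msg, "morbidity targets must lie in [0, 1]")
    if (isTRUE(object@standardized) && anyNA(object@features))
      msg <- c(msg, "standardized pairs must contain no missing values")
    if (is.null(msg)) TRUE else msg
  })

#' Water wave optimization configuration
#'
#' Constants of the wavelength-controlled population search: wavelength
#' reduction coefficient alpha (> 1), tie guard epsilon, breaking coefficient
#' schedule betaStart -> betaEnd (linear in evaluations), maximum number of
#' solitary waves kMax, initial wavelength, population size and evaluation
#' budget.
#'
#' @export
setClass("WWOConfig",
  representation(populationSize = "integer", alpha = "numeric",
                 epsilon = "numeric", betaStart = "numeric",
                 betaEnd = "numeric", kMax = "integer", hMax = "integer",
                 lambdaInit = "numeric", budget = "integer",
                 recomputeFromInit = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@alpha <= 1) msg <- c(msg, "alpha must exceed 1")
    if (object@populationSize < 2L) msg <- c(msg, "populationSize must be >= 2")
    if (object@betaEnd <= 0 || object@betaStart < object@betaEnd)
      msg <- c(msg, "need 0 < betaEnd <= betaStart")
    if (object@lambdaInit <= 0) msg <- c(msg, "lambdaInit must be positive")
    if (object@hMax < 1L) msg <- c(msg, "hMax must be >= 1")
    if (object@budget < 0L) msg <- c(msg, "budget must be nonnegative")
    if (is.null(msg)) TRUE else msg
  })

#' Multiple linear regression model
#' @slot intercept numeric(1).
#' @slot coefficients numeric vector, one per feature.
#' @export
setClass("MLRModel",
  representation(intercept = "numeric", coefficients = "numeric"))

#' Three-layer feed-forward network
#'
#' Input -> hidden -> single sigmoid output. `wIn` is n x m, `thetaHidden`
#' length m, `wOut` length m, `thetaOut` scalar; hidden unit j computes
#' s(sum_i wIn[i,j] x_i - thetaHidden[j]).
#' @export
setClass("ShallowANN",
  representation(wIn = "matrix", thetaHidden = "numeric", wOut = "numeric",
                 thetaOut = "numeric"),
  validity = function(object) {
    m <- ncol(object@wIn)
    if (length(object@thetaHidden) != m || length(object@wOut) != m)
      "hidden dimensions are inconsistent" else TRUE
  })

#' Restricted Boltzmann machine layer
#'
#' @slot w numeric matrix, visible x hidden.
#' @slot b numeric visible bias.
#' @slot c numeric hidden bias.
#' @slot visibleKind `"gaussian"` (bottom layer, standardized real inputs)
#'   or `"bernoulli"`.
#' @export
setClass("RBMLayer",
  representation(w = "matrix", b = "numeric", c = "numeric",
                 visibleKind = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@b) != nrow(object@w)) msg <- c(msg, "|b| must equal nrow(w)")
    if (length(object@c) != ncol(object@w)) msg <- c(msg, "|c| must equal ncol(w)")
    if (!object@visibleKind %in% c("gaussian", "bernoulli"))
      msg <- c(msg, "visibleKind must be 'gaussian' or 'bernoulli'")
    if (is.null(msg)) TRUE else msg
  })

#' (Denoising) autoencoder layer
#'
#' Encode z = s(w x + b), decode x' = s(w' z + b'). `rho` is the masking
#' corruption rate applied to inputs during denoising training (0 = plain
#' autoencoder).
#'
#' @slot w numeric matrix, hidden x visible.
#' @slot b numeric hidden bias.
#' @slot wp numeric matrix, visible x hidden.
#' @slot bp numeric visible bias.
#' @slot rho numeric(1) corruption rate in `[0, 1)`.
#' @export
setClass("AutoencoderLayer",
  representation(w = "matrix", b = "numeric", wp = "matrix", bp = "numeric",
                 rho = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@b) != nrow(object@w)) msg <- c(msg, "|b| must equal nrow(w)")
    if (nrow(object@wp) != ncol(object@w) || ncol(object@wp) != nrow(object@w))
      msg <- c(msg, "decoder must map hidden size back to visible size")
    if (length(object@bp) != nrow(object@wp)) msg <- c(msg, "|bp| must equal nrow(wp)")
    if (object@rho < 0 || object@rho >= 1) msg <- c(msg, "rho must be in [0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' Ordered stack of RBM or autoencoder layers
#' @slot kind `"DBN"`, `"DAE"` or `"DDAE"`.
#' @slot layers list of [RBMLayer-class] or [AutoencoderLayer-class].
#' @slot hiddenSizes integer hidden widths, outermost first.
#' @slot inputDim integer(1) number of features.
#' @export
setClass("DeepStack",
  representation(kind = "character", layers = "list",
                 hiddenSizes = "integer", inputDim = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("DBN", "DAE", "DDAE"))
      msg <- c(msg, "kind must be DBN, DAE or DDAE")
    if (length(object@layers) != length(object@hiddenSizes))
      msg <- c(msg, "hiddenSizes must match the number of layers")
    vis <- object@inputDim
    for (i in seq_along(object@layers)) {
      ly <- object@layers[[i]]
      dims <- if (is(ly, "RBMLayer")) dim(ly@w) else c(ncol(ly@w), nrow(ly@w))
      if (dims[1] != vis)
        msg <- c(msg, sprintf("layer %d visible size %d != expected %d",
                              i, dims[1], vis))
      if (dims[2] != object@hiddenSizes[i])
        msg <- c(msg, sprintf("layer %d hidden size mismatch", i))
      vis <- dims[2]
    }
    if (is.null(msg)) TRUE else msg
  })

#' Gaussian-mixture output head
#'
#' K full-covariance Gaussian components fitted jointly over
#' (top hidden vector z, morbidity y); prediction is the mixture conditional
#' expectation E\[y | z\].
#'
#' @slot weights numeric simplex of length K.
#' @slot means numeric K x (d+1) matrix (z dims then y).
#' @slot covariances numeric array (d+1) x (d+1) x K.
#' @slot zDim integer(1) dimension d of the code vector.
#' @export
setClass("GMMHead",
  representation(weights = "numeric", means = "matrix",
                 covariances = "array", zDim = "integer"),
  validity = function(object) {
    msg <- NULL
    K <- length(object@weights)
    d1 <- object@zDim + 1L
    if (abs(sum(object@weights) - 1) > 1e-8)
      msg <- c(msg, "component weights must sum to 1")
    if (!all(dim(object@means) == c(K, d1)))
      msg <- c(msg, "means must be K x (zDim+1)")
    if (!all(dim(object@covariances) == c(d1, d1, K)))
      msg <- c(msg, "covariances must be (zDim+1) x (zDim+1) x K")
    if (is.null(msg)) TRUE else msg
  })

#' Deep predictor: encoder stack plus Gaussian-mixture head
#' @export
setClass("DeepPredictor",
  representation(stack = "DeepStack", head = "GMMHead", kindLabel = "character"))
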