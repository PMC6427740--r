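#' Aggregate repeated measurements into weekly tuple cells
#'
#' A contaminant indicator may be measured several times within one
#' region-week; the tuple cell takes the arithmetic mean of all its
#' measurements. Cells with no measurement are left missing (NA).
#'
#' @param raw data.frame with columns `region_id`, `week`, `column_id`
#'   (1..nIndicators(schema)) and `value` (finite reals).
#' @param schema a [ContaminantSchema-class].
#' @param grid data.frame with columns `region_id`, `week` enumerating the
#'   tuple slots; defaults to every (region, week) present in `raw`.
#' @return numeric matrix, `nIndicators(schema)` x `nrow(grid)`, with NA in
#'   unmeasured cells; tuple columns ordered as `grid`.
#' @export
aggregateMeasurements <- function(raw, schema, grid = NULL) {
  need <- c("region_id", "week", "column_id", "value")
  stopIfNot(all(need %in% names(raw)),
            "raw needs columns region_id, week, column_id, value")
  n <- nIndicators(schema)
  if (nrow(raw) > 0) {
    if (any(!is.finite(raw$value)))
      stop("non-finite measurement value encountered")
    bad <- raw$column_id < 1L | raw$column_id > n |
      raw$column_id != floor(raw$column_id)
    if (any(bad))
      stop("unknown column id(s): ",
           paste(unique(raw$column_id[bad]), collapse = ", "))
  }
  if (is.null(grid)) {
    grid <- unique(raw[, c("region_id", "week")])
    grid <- grid[order(grid$region_id, grid$week), , drop = FALSE]
  }
  rownames(grid) <- NULL
  tupleKey <- paste(grid$region_id, grid$week)
  out <- matrix(NA_real_, nrow = n, ncol = nrow(grid))
  if (nrow(raw) > 0) {
    ti <- match(paste(raw$region_id, raw$week), tupleKey)
    if (anyNA(ti))
      stop("measurement for a (region, week) absent from the tuple grid")
    cell <- (ti - 1L) * n + as.integer(raw$column_id)
    sums <- rowsum(raw$value, cell)
    cnts <- rowsum(rep(1, nrow(raw)), cell)
    out[as.integer(rownames(sums))] <- sums / cnts
  }
  colnames(out) <- tupleKey
  out
}

#' Weekly morbidity from counts
#'
#' The regression target: disease incidences in a region-week divided by the
#' region's resident population.
#'
#' @param incidences nonnegative counts (vectorized).
#' @param population positive resident counts.
#' @return numeric morbidity values.
#' @export
computeMorbidity <- function(incidences, population) {
  stopIfNot(all(population > 0), "population must be positive")
  stopIfNot(all(incidences >= 0), "incidences must be nonnegative")
  incidences / population
}

#' Mean imputation of missing feature cells
#'
#' Missing cells are filled with the per-column mean of the *training*
#' observed entries; the same training means fill the matrix the model will
#' be applied to, so no statistic ever derives from test tuples. A column
#' with no observed training entry has no defined mean and is filled with 0
#' (after standardization such a column is all zero anyway).
#'
#' @param train numeric matrix (rows = tuples) with NA for missing cells.
#' @param applyTo optional second matrix with the same column count, filled
#'   with the training means.
#' @return list with `train`, `applyTo` (NULL if not given) and `means`.
#' @export
imputeMissing <- function(train, applyTo = NULL) {
  train <- as.matrix(train)
  if (!is.null(applyTo)) {
    applyTo <- as.matrix(applyTo)
    stopIfNot(ncol(applyTo) == ncol(train),
              "train and applyTo must share the column count")
  }
  means <- colMeans(train, na.rm = TRUE)
  means[!is.finite(means)] <- 0      # fully-missing training columns
  fill <- function(m) {
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- means[idx[, 2L]]
    m
  }
  list(train = fill(train), applyTo = if (!is.null(applyTo)) fill(applyTo),
       means = means)
}

#' Z-score features by training-column statistics
#'
#' Columns are centred and scaled with the training mean and standard
#' deviation; a zero-variance training column is set to 0 everywhere. The
#' Gaussian-visible bottom layer of the deep stacks assumes unit-variance
#' inputs, and the evolutionary search uses one weight range for all
#' dimensions, so standardization is applied after imputation throughout.
#'
#' @param train numeric matrix without missing values (rows = tuples).
#' @param applyTo optional matrix transformed with the training statistics.
#' @return list with `train`, `applyTo`, `center`, `scale`.
#' @export
standardizeFeatures <- function(train, applyTo = NULL) {
  train <- as.matrix(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2L, stats::sd)
  dead <- !is.finite(scl) | scl == 0
  scl[dead] <- 1
  zs <- function(m) {
    m <- sweep(sweep(m, 2L, ctr, "-"), 2L, scl, "/")
    m[, dead] <- 0
    m
  }
  list(train = zs(train), applyTo = if (!is.null(applyTo)) zs(as.matrix(applyTo)),
       center = ctr, scale = scl)
}

#' Build time-lagged supervised pairs
#'
#' Pairs the feature vector of week t - lag with one disease's morbidity at
#' week t, within each region separately; a pair exists only when both
#' weeks have a tuple. Output is ordered by (region, target week). Features
#' are returned raw (NA where unobserved) together with the mask; call
#' [preprocessPairs()] per training/test split.
#'
#' @param x a [SurveillanceExperiment-class].
#' @param disease one of `diseases(x)`.
#' @param lag positive integer lag in weeks.
#' @return a [SupervisedPairs-class] (possibly with zero rows).
#' @export
makeLaggedPairs <- function(x, disease, lag) {
  stopIfNot(length(disease) == 1L && disease %in% diseases(x),
            paste("unknown disease:", disease))
  lag <- as.integer(lag)
  stopIfNot(lag >= 1L, "lag must be >= 1 week")
  reg <- regionId(x); wk <- weekIndex(x)
  mb <- morbidity(x)[, disease]
  key <- paste(reg, wk)
  src <- match(paste(reg, wk - lag), key)   # tuple at t - lag, same region
  keep <- which(!is.na(src))
  keep <- keep[order(reg[keep], wk[keep])]
  vals <- featureValues(x)
  feat <- t(vals[, src[keep], drop = FALSE])
  new("SupervisedPairs",
      features = feat, observed = !is.na(feat),
      y = as.numeric(mb[keep]), regionId = reg[keep],
      targetWeek = as.integer(wk[keep]), disease = disease, lag = lag,
      standardized = FALSE)
}

#' @describeIn makeLaggedPairs number of pairs.
#' @param pairs a [SupervisedPairs-class].
#' @export
nPairs <- function(pairs) nrow(pairs@features)

setMethod("show", "SupervisedPairs", function(object) {
  cat("SupervisedPairs:", nrow(object@features), "pairs x",
      ncol(object@features), "features; disease:", object@disease,
      "; lag:", object@lag, "week(s);",
      if (object@standardized) "standardized" else "raw", "\n")
})

#' Subset supervised pairs by row index
#' @param pairs a [SupervisedPairs-class].
#' @param i integer or logical row index.
#' @export
subsetPairs <- function(pairs, i) {
  new("SupervisedPairs",
      features = pairs@features[i, , drop = FALSE],
      observed = pairs@observed[i, , drop = FALSE],
      y = pairs@y[i], regionId = pairs@regionId[i],
      targetWeek = pairs@targetWeek[i], disease = pairs@disease,
      lag = pairs@lag, standardized = pairs@standardized)
}

#' Impute and standardize a training/test split of pairs
#'
#' Applies [imputeMissing()] then [standardizeFeatures()], computing every
#' statistic on the training rows only.
#'
#' @param train,test [SupervisedPairs-class] objects sharing the feature count
#'   (`test` may be NULL).
#' @return list of standardized `train` and `test` pairs plus the
#'   preprocessing statistics (`means`, `center`, `scale`).
#' @export
preprocessPairs <- function(train, test = NULL) {
  imp <- imputeMissing(train@features, if (!is.null(test)) test@features)
  std <- standardizeFeatures(imp$train, imp$applyTo)
  wrap <- function(p, m) {
    p@features <- m
    p@standardized <- TRUE
    validObject(p)
    p
  }
  list(train = wrap(train, std$train),
       test = if (!is.null(test)) wrap(test, std$applyTo),
       means = imp$means, center = std$center, scale = std$scale)
}

#' Random k-fold partition
#'
#' Uniform random assignment of items to k disjoint test folds whose sizes
#' differ by at most one; deterministic for a fixed seed.
#'
#' @param n number of items (or a [SupervisedPairs-class]).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold labels 1..k, length n.
#' @export
splitKfold <- function(n, k, seed) {
  if (is(n, "SupervisedPairs")) n <- nPairs(n)
  n <- as.integer(n); k <- as.integer(k)
  stopIfNot(k >= 2L, "k must be >= 2")
  stopIfNot(n >= k, "need at least k items to form k folds")
  base <- rep(seq_len(k), length.out = n)
  withSeed(seed, base[sample.int(n)])
}
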