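#' Configuration for the synthetic surveillance generator
#'
#' The generator emulates the statistical structure the prediction models
#' assume in region-week food-contamination surveillance: per-region
#' autocorrelated contamination levels, heavy missingness, and sparse lagged
#' (optionally nonlinear) contamination -> morbidity effects whose strength
#' differs by disease, with a near-zero-signal "tumor-like" disease.
#'
#' Defaults are desk scale: 12 foods x 20 contaminants (240 indicator
#' columns), 4 regions, 60 weeks, 18% observed cells (the observed share of
#' indicator cells in the motivating ten-city surveillance table), six
#' diseases with lags of 1-4 weeks. Morbidity scales are weekly
#' incidence-per-resident rates of order 1e-4.
#'
#' @param nFoods,nContaminants schema dimensions.
#' @param nRegions,nWeeks tuple grid dimensions.
#' @param observedFraction probability a feature cell is measured.
#' @param diseases character labels.
#' @param nActive number of truly influential indicator columns per disease.
#' @param lagTrue integer lag (weeks) per disease.
#' @param effectWeights list of per-disease weight vectors over the active
#'   columns (default: geometric decay, normalized to sum 1).
#' @param link `"sigmoid"` (nonlinear, default) or `"linear"` response link.
#' @param intercept offset added to the weighted active-column sum before
#'   the link (default 0; a positive intercept keeps a linear-link response
#'   away from the clip at 0).
#' @param signalScale per-disease morbidity scale (tumor-like disease 0).
#' @param noiseSd additive Gaussian noise sd on the morbidity scale.
#' @param measurementSd sd of measurement noise added to observed cells.
#' @param arCoef AR(1) coefficient of the latent contamination level.
#' @param populationRange range of per-region resident populations.
#' @param seed integer seed; the full dataset is a deterministic function of
#'   the configuration.
#' @return a validated `SyntheticConfig` list.
#' @export
syntheticConfig <- function(nFoods = 12L, nContaminants = 20L, nRegions = 4L,
                            nWeeks = 60L, observedFraction = 0.18,
                            diseases = c("acute_gastroenteritis",
                                         "chronic_gastroenteritis",
                                         "gastrointestinal_ulcers",
                                         "gastrointestinal_tumors",
                                         "food_poisoning",
                                         "other_infections"),
                            nActive = 8L,
                            lagTrue = c(1L, 3L, 3L, 4L, 1L, 1L),
                            effectWeights = NULL,
                            link = c("sigmoid", "linear"), intercept = 0,
                            signalScale = c(6e-4, 4e-4, 4e-4, 0, 8e-4, 5e-4),
                            noiseSd = 4e-5, measurementSd = 0.3,
                            arCoef = 0.7,
                            populationRange = c(2e5, 8e5), seed = 1L) {
  link <- match.arg(link)
  nd <- length(diseases)
  if (length(lagTrue) == 1L) lagTrue <- rep(lagTrue, nd)
  if (length(signalScale) == 1L) signalScale <- rep(signalScale, nd)
  n <- nFoods * nContaminants
  stopIfNot(length(lagTrue) == nd && length(signalScale) == nd,
            "lagTrue and signalScale must have one entry per disease")
  stopIfNot(all(lagTrue >= 1L), "lagTrue must be >= 1")
  stopIfNot(nActive <= n, "nActive cannot exceed the indicator count")
  stopIfNot(observedFraction > 0 && observedFraction <= 1,
            "observedFraction must lie in (0, 1]")
  stopIfNot(noiseSd >= 0, "noiseSd must be nonnegative")
  if (is.null(effectWeights)) {
    w <- 0.6 ^ (seq_len(nActive) - 1L)
    effectWeights <- rep(list(w / sum(w)), nd)
  }
  stopIfNot(length(effectWeights) == nd &&
              all(vapply(effectWeights, length, 1L) == nActive),
            "effectWeights must be one length-nActive vector per disease")
  structure(list(nFoods = as.integer(nFoods),
                 nContaminants = as.integer(nContaminants),
                 nRegions = as.integer(nRegions), nWeeks = as.integer(nWeeks),
                 observedFraction = observedFraction,
                 diseases = as.character(diseases),
                 nActive = as.integer(nActive), lagTrue = as.integer(lagTrue),
                 effectWeights = effectWeights, link = link,
                 intercept = intercept,
                 signalScale = as.numeric(signalScale), noiseSd = noiseSd,
                 measurementSd = measurementSd, arCoef = arCoef,
                 populationRange = populationRange, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

.linkFun <- function(link) switch(link, linear = identity, sigmoid = sigmoid)

#' Generate a synthetic surveillance dataset with planted effects
#'
#' Contamination columns follow a per-region AR(1) latent level; observed
#' cells add measurement noise and an independent Bernoulli(observedFraction)
#' mask decides which cells were measured. Morbidity of disease d at week t
#' is `clip01(signalScale[d] * link(sum(w * latent_active(t - lagTrue[d]))) +
#' N(0, noiseSd))`, computed from the uncorrupted latent levels, then
#' quantized to incidence counts over the region population (so the stored
#' target equals incidences / population exactly, and matches the intended
#' morbidity to count resolution, i.e. within 0.5 / population).
#'
#' @param cfg a [syntheticConfig()].
#' @return list with `experiment` (a [SurveillanceExperiment-class]) and
#'   `groundTruth`: active column ids, weights, lags, scales, link, noise sd,
#'   and the per-tuple noiseless and realized (pre-quantization) morbidity.
#' @export
generateDataset <- function(cfg) {
  stopIfNot(inherits(cfg, "SyntheticConfig"), "cfg must be a SyntheticConfig")
  schema <- ContaminantSchema(sprintf("food%02d", seq_len(cfg$nFoods)),
                              sprintf("contaminant%03d",
                                      seq_len(cfg$nContaminants)))
  n <- nIndicators(schema)
  nd <- length(cfg$diseases)
  maxLag <- max(cfg$lagTrue)
  nT <- cfg$nRegions * cfg$nWeeks
  withSeed(cfg$seed, {
    active <- lapply(seq_len(nd), function(d) sort(sample.int(n, cfg$nActive)))
    pop <- as.integer(round(runif(cfg$nRegions, cfg$populationRange[1],
                                  cfg$populationRange[2])))
    linkF <- .linkFun(cfg$link)
    vals <- matrix(NA_real_, n, nT)
    noiseless <- matrix(NA_real_, nT, nd)
    realized <- matrix(NA_real_, nT, nd)
    inc <- matrix(NA_integer_, nT, nd)
    regionIds <- sprintf("region%02d", seq_len(cfg$nRegions))
    col0 <- 0L
    for (r in seq_len(cfg$nRegions)) {
      wExt <- cfg$nWeeks + maxLag        # weeks -maxLag .. nWeeks-1
      lat <- matrix(0, n, wExt)
      lat[, 1L] <- rnorm(n, 0, 1 / sqrt(1 - cfg$arCoef^2))
      for (t in 2:wExt)
        lat[, t] <- cfg$arCoef * lat[, t - 1L] + rnorm(n)
      cur <- lat[, (maxLag + 1L):wExt, drop = FALSE]  # weeks 0..nWeeks-1
      meas <- cur + matrix(rnorm(n * cfg$nWeeks, 0, cfg$measurementSd),
                           n, cfg$nWeeks)
      mask <- matrix(runif(n * cfg$nWeeks) <= cfg$observedFraction,
                     n, cfg$nWeeks)
      meas[!mask] <- NA_real_
      idx <- col0 + seq_len(cfg$nWeeks)
      vals[, idx] <- meas
      for (d in seq_len(nd)) {
        lagged <- lat[, (maxLag + 1L - cfg$lagTrue[d]):
                        (wExt - cfg$lagTrue[d]), drop = FALSE]
        eta <- cfg$intercept +
          as.numeric(crossprod(lagged[active[[d]], , drop = FALSE],
                               cfg$effectWeights[[d]]))
        clean <- pmin(1, pmax(0, cfg$signalScale[d] * linkF(eta)))
        noisy <- pmin(1, pmax(0, clean + rnorm(cfg$nWeeks, 0, cfg$noiseSd)))
        noiseless[idx, d] <- clean
        realized[idx, d] <- noisy
        inc[idx, d] <- as.integer(round(noisy * pop[r]))
      }
      col0 <- col0 + cfg$nWeeks
    }
  })
  region <- rep(regionIds, each = cfg$nWeeks)
  week <- rep(0:(cfg$nWeeks - 1L), times = cfg$nRegions)
  exp <- SurveillanceExperiment(schema, vals, region, week,
                                rep(pop, each = cfg$nWeeks), inc,
                                cfg$diseases)
  gt <- structure(list(activeColumns = active,
                       effectWeights = cfg$effectWeights,
                       lagTrue = cfg$lagTrue, signalScale = cfg$signalScale,
                       link = cfg$link, intercept = cfg$intercept,
                       noiseSd = cfg$noiseSd,
                       diseases = cfg$diseases, noiseless = noiseless,
                       realized = realized),
                  class = "SyntheticGroundTruth")
  list(experiment = exp, groundTruth = gt)
}

#' Noiseless planted response for a feature vector
#'
#' Evaluates the generator's clean response surface: the morbidity that the
#' planted model assigns to latent feature vector `x` for one disease,
#' before noise and count quantization.
#'
#' @param gt `groundTruth` component of [generateDataset()].
#' @param x numeric feature vector of full indicator length (latent scale).
#' @param disease disease label.
#' @return numeric(1) morbidity in `[0, 1]`.
#' @export
trueResponse <- function(gt, x, disease) {
  d <- match(disease, gt$diseases)
  if (is.na(d)) stop("unknown disease: ", disease)
  eta <- gt$intercept + sum(gt$effectWeights[[d]] * x[gt$activeColumns[[d]]])
  pmin(1, pmax(0, gt$signalScale[d] * .linkFun(gt$link)(eta)))
}

#' Strong-signal configuration for planted-lag recovery studies
#'
#' A variant of the default desk-scale configuration designed so that the
#' planted lag is identifiable by a linear model: linear link with a
#' positive intercept (no clipping at zero), high observed fraction, low
#' measurement and response noise, and one shared lag for every disease.
#' Used by the lag-sweep recovery tests; the default [syntheticConfig()]
#' remains the benchmark condition.
#'
#' @param lagTrue the planted lag in weeks (default 3).
#' @param seed integer seed.
#' @return a `SyntheticConfig`.
#' @export
strongSignalConfig <- function(lagTrue = 3L, seed = 1L) {
  syntheticConfig(link = "linear", intercept = 3, observedFraction = 0.9,
                  measurementSd = 0.1, noiseSd = 1e-5,
                  signalScale = rep(2e-4, 6), lagTrue = rep(lagTrue, 6L),
                  nActive = 5L, seed = seed)
}
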