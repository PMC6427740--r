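# Fixtures shared across test files; everything is built in code.

# A tiny two-region experiment with known feature values and gaps.
# Region A has weeks 0..5, region B weeks 0,1,2,4,5 (gap at 3).
tinyExperiment <- function() {
  schema <- ContaminantSchema(c("rice", "pork"), c("Pb", "Cd"))
  weeks <- c(0:5, 0L, 1L, 2L, 4L, 5L)
  regions <- c(rep("A", 6), rep("B", 5))
  nT <- length(weeks)
  set.seed(7)
  vals <- matrix(rnorm(4 * nT), 4, nT)
  vals[cbind(sample.int(4, nT, replace = TRUE), seq_len(nT))] <- NA
  inc <- cbind(gastritis = rpois(nT, 30), ulcers = rpois(nT, 10))
  SurveillanceExperiment(schema, vals, regions, weeks,
                         population = rep(c(120000L, 90000L), c(6, 5)),
                         incidences = inc,
                         diseases = c("gastritis", "ulcers"),
                         week0Date = "2015-05-04")
}

# Standardized toy supervised data: y = s(scale * (x1 - x2)) morphed into
# [0, 1]; small enough for every model kind.
toyPairs <- function(n = 100L, p = 12L, seed = 5L) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  y <- 0.4 * plogis(1.5 * (x[, 1] - x[, 2])) + rnorm(n, 0, 0.01)
  y <- pmin(1, pmax(0, y))
  list(x = x, y = y)
}

# small TrainSpec for deep-model unit tests
tinySpec <- function(seed = 1L, ...) {
  trainSpec(hiddenSizes = c(6L, 3L), epochs = 5L, preEpochs = 3L,
            gmmK = 2L,
            wwoPre = wwoConfig(populationSize = 6L, budget = 60L),
            wwoFine = wwoConfig(populationSize = 6L, budget = 80L,
                                lambdaInit = 0.001),
            seed = seed, ...)
}
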