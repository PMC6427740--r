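test_that("weekly aggregation takes the mean of repeated measurements", {
  sc <- ContaminantSchema(c("rice", "pork"), c("Pb", "Cd"))
  raw <- data.frame(region_id = c("A", "A", "A"),
                    week = c(0L, 0L, 0L),
                    column_id = c(1L, 1L, 3L),
                    value = c(4.0, 6.0, 3.2))
  out <- aggregateMeasurements(raw, sc)
  expect_equal(unname(out[1, 1]), 5.0)   # mean of two measurements
  expect_equal(unname(out[3, 1]), 3.2)   # single measurement passes through
  expect_true(is.na(out[2, 1]))          # unmeasured cell stays missing
})

test_that("aggregation matches a brute-force group-by-mean oracle", {
  sc <- ContaminantSchema(sprintf("f%d", 1:5), sprintf("c%d", 1:8))
  set.seed(11)
  cells <- data.frame(region_id = sample(c("A", "B"), 1000, TRUE),
                      week = sample(0:9, 1000, TRUE),
                      column_id = sample.int(40, 1000, TRUE))
  raw <- cells[rep(seq_len(1000), sample(1:4, 1000, TRUE)), ]
  raw$value <- rnorm(nrow(raw))
  out <- aggregateMeasurements(raw, sc)
  key <- paste(raw$region_id, raw$week)
  oracle <- tapply(raw$value,
                   list(paste(key, raw$column_id)), mean)
  for (nm in sample(names(oracle), 50)) {
    parts <- strsplit(nm, " ")[[1]]
    col <- paste(parts[1], parts[2])
    expect_equal(unname(out[as.integer(parts[3]), col]),
                 unname(oracle[[nm]]))
  }
})

test_that("aggregation validates columns and values", {
  sc <- ContaminantSchema("rice", "Pb")
  bad <- data.frame(region_id = "A", week = 0L, column_id = 2L, value = 1)
  expect_error(aggregateMeasurements(bad, sc), "unknown column")
  inf <- data.frame(region_id = "A", week = 0L, column_id = 1L, value = Inf)
  expect_error(aggregateMeasurements(inf, sc), "non-finite")
})

test_that("morbidity is incidences over population", {
  expect_equal(computeMorbidity(0, 50000), 0)
  expect_equal(computeMorbidity(5, 100000), 5e-5)
  expect_equal(computeMorbidity(1234, 987654), 1234 / 987654,
               tolerance = 1e-15)
  expect_error(computeMorbidity(5, 0), "population")
  expect_error(computeMorbidity(-1, 10), "nonnegative")
})

test_that("mean imputation uses training statistics only", {
  train <- matrix(c(1, NA, 3, 2, 2, 2), ncol = 2)
  test <- matrix(c(NA, 5, NA, NA), ncol = 2)
  out <- imputeMissing(train, test)
  expect_equal(out$train[2, 1], 2)            # mean of 1 and 3
  expect_equal(out$applyTo[1, 1], 2)          # filled with the training mean
  expect_equal(out$applyTo[2, 1], 5)          # observed cells unchanged
  expect_equal(out$applyTo[, 2], c(2, 2))     # constant training column
  # a column with no missing values passes through untouched
  expect_equal(out$train[, 2], train[, 2])
})

test_that("imputation is idempotent and matches a per-column oracle", {
  set.seed(3)
  m <- matrix(rnorm(1000), 50, 20)
  m[sample(length(m), 300)] <- NA
  once <- imputeMissing(m)$train
  twice <- imputeMissing(once)$train
  expect_identical(once, twice)
  for (j in seq_len(20)) {
    mu <- mean(m[, j], na.rm = TRUE)
    expect_equal(once[is.na(m[, j]), j],
                 rep(mu, sum(is.na(m[, j]))))
  }
  # fully-missing training column is filled with zero
  m[, 4] <- NA
  expect_equal(imputeMissing(m)$train[, 4], rep(0, 50))
})

test_that("standardization z-scores by training statistics", {
  set.seed(4)
  tr <- matrix(rnorm(200, 5, 2), 20, 10)
  te <- matrix(rnorm(100, 5, 2), 10, 10)
  out <- standardizeFeatures(tr, te)
  expect_equal(colMeans(out$train), rep(0, 10), tolerance = 1e-12)
  expect_equal(apply(out$train, 2, sd), rep(1, 10), tolerance = 1e-12)
  expect_equal(out$applyTo, sweep(sweep(te, 2, colMeans(tr)), 2,
                                  apply(tr, 2, sd), "/"))
  tr[, 3] <- 7                             # zero-variance column -> all 0
  out2 <- standardizeFeatures(tr, te)
  expect_equal(out2$train[, 3], rep(0, 20))
  expect_equal(out2$applyTo[, 3], rep(0, 10))
})

test_that("lagged pairs respect regions, gaps and ordering", {
  x <- tinyExperiment()
  p1 <- makeLaggedPairs(x, "gastritis", 1)
  # region A contributes 5 pairs (weeks 0..5), region B 3 (gap at week 3)
  expect_equal(nPairs(p1), 8L)
  expect_equal(sum(p1@regionId == "A"), 5L)
  mb <- morbidity(x)[, "gastritis"]
  wk <- weekIndex(x); rg <- regionId(x)
  # pair features come from the tuple one week before the target
  i <- which(p1@regionId == "A" & p1@targetWeek == 3L)
  src <- which(rg == "A" & wk == 2L)
  expect_equal(unname(p1@features[i, ]), unname(featureValues(x)[, src]))
  expect_equal(p1@y[i], unname(mb[rg == "A" & wk == 3L]))
  # brute-force enumeration oracle at lag 3
  p3 <- makeLaggedPairs(x, "ulcers", 3)
  expected <- 0L
  for (r in c("A", "B")) {
    wks <- wk[rg == r]
    expected <- expected + sum((wks - 3L) %in% wks)
  }
  expect_equal(nPairs(p3), expected)
  # ordering by (region, target week)
  expect_false(is.unsorted(order(p3@regionId, p3@targetWeek)))
  # lag beyond the span yields an empty object, not an error
  expect_equal(nPairs(makeLaggedPairs(x, "gastritis", 20)), 0L)
})

test_that("gap-free lag count is exactly weeks minus lag", {
  cfg <- syntheticConfig(nFoods = 2L, nContaminants = 3L, nRegions = 2L,
                         nWeeks = 15L, nActive = 3L, seed = 8)
  x <- generateDataset(cfg)$experiment
  for (lag in c(1L, 4L, 8L)) {
    p <- makeLaggedPairs(x, "food_poisoning", lag)
    expect_equal(nPairs(p), 2L * (15L - lag))
  }
})

test_that("k-fold splits partition the pairs with balanced sizes", {
  f <- splitKfold(1780L, 5L, seed = 1)
  expect_true(all(table(f) == 356L))
  f2 <- splitKfold(103L, 5L, seed = 9)
  expect_equal(as.integer(sort(table(f2))), c(20L, 20L, 21L, 21L, 21L))
  expect_identical(splitKfold(10L, 5L, seed = 3), splitKfold(10L, 5L, seed = 3))
  expect_error(splitKfold(4L, 5L, seed = 1), "at least k")
  # partition property across random cases
  for (s in 1:5) {
    n <- sample(10:60, 1)
    f <- splitKfold(n, 4L, seed = s)
    expect_equal(length(f), n)
    expect_true(all(f %in% 1:4))
    expect_true(max(table(f)) - min(table(f)) <= 1L)
  }
})

test_that("preprocessing leaves no missing values and flags the pairs", {
  x <- tinyExperiment()
  p <- makeLaggedPairs(x, "gastritis", 1)
  folds <- splitKfold(nPairs(p), 2L, seed = 1)
  prep <- preprocessPairs(subsetPairs(p, folds == 1), subsetPairs(p, folds == 2))
  expect_false(anyNA(prep$train@features))
  expect_false(anyNA(prep$test@features))
  expect_true(prep$train@standardized)
})
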