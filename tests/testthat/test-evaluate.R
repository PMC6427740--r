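test_that("rmse matches the closed form and a loop oracle", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(19)
  a <- rnorm(1000); b <- rnorm(1000)
  loop <- sqrt(sum(vapply(seq_along(a), function(i) (a[i] - b[i])^2,
                          numeric(1))) / 1000)
  expect_equal(rmse(a, b), loop, tolerance = 1e-12)
  expect_equal(rmse(a, b), rmse(b, a))                 # symmetry
  expect_error(rmse(1:3, 1:4), "length")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("accuracy is the complement of total relative error", {
  expect_equal(accuracyPct(c(1, 2), c(1, 2)), 100)
  expect_equal(accuracyPct(c(0, 0), c(1, 2)), 0)
  expect_equal(accuracyPct(c(0.9, 1.1), c(1, 1)), 90)
  expect_equal(accuracyPct(c(10, 0), c(1, 1)), 0)      # clipped at zero
  expect_equal(accuracyPct(c(0, 0), c(0, 0)), 100)
  expect_equal(accuracyPct(c(0.1, 0), c(0, 0)), 0)
  # scale invariance
  set.seed(23)
  a <- runif(50); e <- runif(50)
  expect_equal(accuracyPct(a, e), accuracyPct(3.7 * a, 3.7 * e),
               tolerance = 1e-12)
  expect_error(accuracyPct(1:2, c(-1, 1)), "nonnegative")
})

test_that("cross-validation isolates training statistics per fold", {
  x <- generateDataset(syntheticConfig(nFoods = 4L, nContaminants = 5L,
                                       nRegions = 2L, nWeeks = 30L,
                                       seed = 2))$experiment
  cv <- crossValidate("MLR", x, "food_poisoning", lag = 1, k = 5, seed = 3)
  expect_equal(nrow(cv), 5L)
  expect_equal(sum(cv$nTest), nPairs(makeLaggedPairs(x, "food_poisoning", 1)))
  expect_equal(attr(cv, "meanRmse"), mean(cv$rmse))
  expect_equal(attr(cv, "meanAccuracy"), mean(cv$accuracy))
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 100))
})

test_that("a constant-target disease is predicted perfectly", {
  # constant targets: every model interpolates; MLR gives accuracy 100
  sc <- ContaminantSchema(c("f1", "f2"), c("c1", "c2"))
  set.seed(4)
  nT <- 40L
  vals <- matrix(rnorm(4 * nT), 4, nT)
  x <- SurveillanceExperiment(sc, vals,
                              regionId = rep("A", nT), week = 0:(nT - 1),
                              population = rep(100000L, nT),
                              incidences = cbind(flat = rep(20L, nT)),
                              diseases = "flat")
  cv <- crossValidate("MLR", x, "flat", lag = 1, k = 5, seed = 1)
  expect_equal(cv$accuracy, rep(100, 5))
  expect_equal(cv$rmse, rep(0, 5), tolerance = 1e-10)
})

test_that("permuting held-out targets cannot change the trained model", {
  toy <- toyPairs(60, 6)
  trainIdx <- 1:40
  m1 <- trainModel("MLR", toy$x[trainIdx, ], toy$y[trainIdx])
  yPerm <- toy$y
  yPerm[41:60] <- sample(yPerm[41:60])
  m2 <- trainModel("MLR", toy$x[trainIdx, ], yPerm[trainIdx])
  expect_identical(m1@coefficients, m2@coefficients)
  expect_identical(m1@intercept, m2@intercept)
})

test_that("the lag sweep reports one entry per lag and breaks ties low", {
  x <- generateDataset(syntheticConfig(nFoods = 3L, nContaminants = 4L,
                                       nRegions = 2L, nWeeks = 25L,
                                       seed = 5))$experiment
  sw <- lagSweep("MLR", x, "food_poisoning", lags = 1:8, k = 3, seed = 2)
  expect_equal(sw$curve$lag, 1:8)
  expect_equal(sw$bestLag,
               sw$curve$lag[which.min(sw$curve$meanRmse)])
  # all-equal curve (constant targets) resolves to the smallest lag
  sc <- ContaminantSchema("f", "c")
  nT <- 30L
  set.seed(6)
  cx <- SurveillanceExperiment(sc, matrix(rnorm(nT), 1, nT),
                               regionId = rep("A", nT), week = 0:(nT - 1),
                               population = rep(50000L, nT),
                               incidences = cbind(flat = rep(10L, nT)),
                               diseases = "flat")
  swFlat <- lagSweep("MLR", cx, "flat", lags = 1:4, k = 3, seed = 1)
  expect_equal(swFlat$bestLag, 1L)
})

test_that("model comparison summarises fold metrics consistently", {
  x <- generateDataset(syntheticConfig(nFoods = 4L, nContaminants = 5L,
                                       nRegions = 2L, nWeeks = 30L,
                                       seed = 7))$experiment
  cmp <- compareModels(x, kinds = c("MLR", "ANN"),
                       diseaseSet = c("food_poisoning",
                                      "gastrointestinal_tumors"),
                       lags = 1L, k = 2L,
                       spec = trainSpec(epochs = 3L), seed = 4)
  s <- attr(cmp, "summary")
  expect_equal(nrow(s), 4L)                 # 2 kinds x 2 diseases
  expect_equal(nrow(cmp), 8L)               # x 2 folds
  for (i in seq_len(nrow(s))) {
    rows <- cmp[cmp$model == s$model[i] & cmp$disease == s$disease[i], ]
    expect_equal(s$meanRmse[i], mean(rows$rmse))
    expect_equal(s$meanAccuracy[i], mean(rows$accuracy))
  }
})
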