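test_that("layerwise pretraining chains codes and records losses", {
  toy <- toyPairs(60, 10)
  for (kind in c("DBN", "DAE", "DDAE")) {
    st <- deepStack(kind, 10L, c(5L, 3L), seed = 2)
    sp <- tinySpec(seed = 2)
    tr <- pretrainGradient(st, toy$x, sp)
    hist <- attr(tr, "lossHistory")
    expect_length(hist, 2L)
    expect_true(all(vapply(hist, length, 1L) == sp$preEpochs))
    # layer-2 input dimensionality equals layer-1 hidden size
    codes1 <- evomorbid:::layerEncode(tr@layers[[1]], toy$x)
    expect_equal(ncol(codes1), 5L)
    expect_equal(ncol(evomorbid:::layerEncode(tr@layers[[2]], codes1)), 3L)
  }
})

test_that("zero pretraining epochs leave the stack unchanged", {
  st <- deepStack("DAE", 8L, c(4L, 2L), seed = 5)
  sp <- tinySpec(seed = 1); sp$preEpochs <- 0L
  tr <- pretrainGradient(st, toyPairs(30, 8)$x, sp)
  expect_identical(flattenParams(tr), flattenParams(st))
})

test_that("autoencoder pretraining reduces the layer-1 loss", {
  toy <- toyPairs(200, 12, seed = 9)
  st <- deepStack("DAE", 12L, c(6L, 3L), seed = 3)
  sp <- tinySpec(seed = 3); sp$preEpochs <- 15L; sp$preLr <- 0.3
  tr <- pretrainGradient(st, toy$x, sp)
  l1 <- attr(tr, "lossHistory")[[1]]
  expect_lt(l1[length(l1)], l1[1])
})

test_that("gradient fine-tuning never returns worse than the pretrained model", {
  toy <- toyPairs(80, 10)
  st <- pretrainGradient(deepStack("DAE", 10L, c(5L, 3L), seed = 4),
                         toy$x, tinySpec(seed = 4))
  ft <- finetuneGradient(st, toy$x, toy$y, tinySpec(seed = 4))
  expect_lte(attr(ft, "trainRmse"), attr(ft, "pretrainRmse") + 1e-12)
  # lr = 0: encoder parameters stay at the pretrained values
  sp0 <- tinySpec(seed = 4); sp0$lr <- 0
  ft0 <- finetuneGradient(st, toy$x, toy$y, sp0)
  expect_identical(evomorbid:::encoderParams(ft0@stack),
                   evomorbid:::encoderParams(st))
})

test_that("encoder gradient matches finite differences on a small toy", {
  set.seed(6)
  X <- matrix(rnorm(80), 20, 4)
  y <- pmin(1, pmax(0, 0.3 + 0.2 * tanh(X[, 1]) + rnorm(20, 0, 0.02)))
  stack <- pretrainGradient(deepStack("DAE", 4L, c(3L, 2L), seed = 6),
                            X, tinySpec(seed = 6))
  head <- gmmFitJoint(stackEncode(stack, X), y, K = 2L, seed = 21)
  v0 <- evomorbid:::encoderParams(stack)
  lr <- 1e-3
  analytic <- (v0 - evomorbid:::finetuneStepOnce(stack, head, X, y, lr)) / lr
  lossFn <- function(v) {
    z <- stackEncode(evomorbid:::setEncoderParams(stack, v), X)
    mean((gmmPredict(head, z) - y)^2)
  }
  eps <- 1e-6
  for (i in sample(seq_along(v0), 12)) {
    e <- numeric(length(v0)); e[i] <- eps
    fd <- (lossFn(v0 + e) - lossFn(v0 - e)) / (2 * eps)
    expect_lt(abs(analytic[i] - fd), 1e-4)
  }
})

test_that("evolutionary pretraining is deterministic and bounded", {
  toy <- toyPairs(40, 8)
  st <- deepStack("DAE", 8L, c(4L, 2L), seed = 7)
  sp <- tinySpec(seed = 7)
  a <- pretrainEvolutionary(st, toy$x, sp)
  b <- pretrainEvolutionary(st, toy$x, sp)
  expect_identical(flattenParams(a), flattenParams(b))
  expect_true(all(abs(flattenParams(a)) <= 4 + 1e-12))
  # budget 0: best of the initial population per layer, still valid
  sp0 <- tinySpec(seed = 7)
  sp0$wwoPre <- wwoConfig(populationSize = 4L, budget = 0L)
  z <- pretrainEvolutionary(st, toy$x, sp0)
  expect_s4_class(z, "DeepStack")
  expect_true(validObject(z))
})

test_that("evolutionary fine-tuning keeps the elitism contract", {
  toy <- toyPairs(60, 8)
  st <- deepStack("DAE", 8L, c(4L, 2L), seed = 8)
  sp <- tinySpec(seed = 8)
  pre <- pretrainEvolutionary(st, toy$x, sp)
  ft <- finetuneEvolutionary(pre, toy$x, toy$y, sp)
  expect_lte(attr(ft, "trainRmse"), attr(ft, "pretrainRmse") + 1e-12)
  # budget 0 returns the pretrained model unchanged
  sp0 <- tinySpec(seed = 8)
  sp0$wwoFine <- wwoConfig(populationSize = 4L, budget = 0L,
                           lambdaInit = 0.001)
  ft0 <- finetuneEvolutionary(pre, toy$x, toy$y, sp0)
  expect_identical(evomorbid:::encoderParams(ft0@stack),
                   evomorbid:::encoderParams(pre))
})

test_that("the denoising stack at rate zero equals the plain stack", {
  toy <- toyPairs(60, 10)
  for (pair in list(c("DAE", "DDAE"), c("EvoDAE", "EvoDDAE"))) {
    spA <- tinySpec(seed = 11)
    spB <- tinySpec(seed = 11); spB$rho <- 0
    a <- trainModel(pair[1], toy$x, toy$y, spA)
    b <- trainModel(pair[2], toy$x, toy$y, spB)
    expect_identical(flattenParams(a@stack), flattenParams(b@stack))
    expect_identical(a@head@means, b@head@means)
  }
})

test_that("the dispatcher covers all eight kinds with a uniform contract", {
  toy <- toyPairs(100, 12)
  for (kind in c("MLR", "ANN", "DBN", "EvoDBN", "DAE", "EvoDAE", "DDAE",
                 "EvoDDAE")) {
    m <- trainModel(kind, toy$x, toy$y, tinySpec(seed = 12))
    pred <- predictMorbidity(m, toy$x[1:7, ])
    expect_length(pred, 7L)
    expect_true(all(is.finite(pred)))
    expect_true(all(pred >= 0 & pred <= 1))
  }
  expect_error(trainModel("XGB", toy$x, toy$y), "arg")
  # MLR delegation recovers a noiseless linear toy
  x <- matrix(rnorm(60), 60, 1)
  m <- trainModel("MLR", x, 0.2 + 0.1 * x[, 1])
  expect_equal(m@coefficients, 0.1, tolerance = 1e-7)
})

test_that("evolutionary fine-tuning improves on pretraining at desk scale", {
  # 240-feature benchmark data, 24-8 stack, median over 5 seeds
  gd <- generateDataset(syntheticConfig(seed = 4))
  p <- makeLaggedPairs(gd$experiment, "food_poisoning", 1)
  folds <- splitKfold(nPairs(p), 5L, seed = 1)
  prep <- preprocessPairs(subsetPairs(p, folds != 1), NULL)
  pre <- post <- numeric(5)
  for (s in 1:5) {
    sp <- trainSpec(hiddenSizes = c(24L, 8L), seed = s)
    m <- trainModel("EvoDAE", prep$train@features, prep$train@y, sp)
    pre[s] <- attr(m, "pretrainRmse"); post[s] <- attr(m, "trainRmse")
    expect_lte(post[s], pre[s] + 1e-15)
  }
  expect_lt(median(post), median(pre))
})
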