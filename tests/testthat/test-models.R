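test_that("sigmoid is symmetric, bounded and matches high precision", {
  expect_equal(sigmoid(0), 0.5)
  for (u in c(-5, -1, 0.3, 8))
    expect_equal(sigmoid(u) + sigmoid(-u), 1, tolerance = 1e-15)
  expect_equal(sigmoid(2), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_true(all(sigmoid(c(-700, 700)) >= 0 & sigmoid(c(-700, 700)) <= 1))
  expect_gt(sigmoid(-700), 0)
})

test_that("MLR recovers planted linear coefficients", {
  set.seed(2)
  x <- matrix(rnorm(50), 50, 1)
  y <- 1 + 2 * x[, 1]
  m <- mlrFit(x, y)
  expect_equal(m@intercept, 1, tolerance = 1e-8)
  expect_equal(m@coefficients, 2, tolerance = 1e-8)
  expect_equal(mlrPredict(m, matrix(0.3)), 1.6, tolerance = 1e-7)
})

test_that("MLR handles degenerate targets and matches normal equations", {
  set.seed(3)
  x <- matrix(rnorm(80), 20, 4)
  m <- mlrFit(x, rep(0.25, 20))
  expect_equal(m@intercept, 0.25, tolerance = 1e-10)
  expect_equal(m@coefficients, rep(0, 4), tolerance = 1e-8)
  # random 40 x 8 problem vs brute-force normal-equations oracle
  x <- matrix(rnorm(320), 40, 8)
  y <- rnorm(40)
  m <- mlrFit(x, y)
  X1 <- cbind(1, x)
  beta <- solve(crossprod(X1), crossprod(X1, y))
  oracleRmse <- sqrt(mean((X1 %*% beta - y)^2))
  expect_equal(rmse(mlrPredict(m, x), y), oracleRmse, tolerance = 1e-8)
  # n > N path (dual form) interpolates noiseless data
  xw <- matrix(rnorm(10 * 30), 10, 30)
  yw <- xw %*% rnorm(30)
  mw <- mlrFit(xw, as.numeric(yw))
  expect_lt(rmse(mlrPredict(mw, xw), as.numeric(yw)), 1e-6)
})

test_that("shallow network forward pass follows the two-step sigmoid chain", {
  # all-zero network: hidden outputs 0.5, final output s(0) = 0.5
  m0 <- new("ShallowANN", wIn = matrix(0, 3, 2), thetaHidden = c(0, 0),
            wOut = c(0, 0), thetaOut = 0)
  expect_equal(annForward(m0, c(1, 2, 3)), 0.5)
  # 1-1-1 network vs hand computation
  m1 <- new("ShallowANN", wIn = matrix(0.7), thetaHidden = 0.2,
            wOut = -1.3, thetaOut = 0.4)
  x <- 0.9
  z <- 1 / (1 + exp(-(0.7 * x - 0.2)))
  yhat <- 1 / (1 + exp(-(-1.3 * z - 0.4)))
  expect_equal(annForward(m1, x), yhat, tolerance = 1e-14)
  expect_error(annForward(m1, c(1, 2)), "dimension")
  # outputs always inside (0, 1)
  set.seed(9)
  for (i in 1:20) {
    mr <- shallowANN(4, 3, seed = i)
    out <- annForward(mr, matrix(rnorm(200), 50, 4))
    expect_true(all(out > 0 & out < 1))
  }
})

test_that("backprop gradient matches finite differences and training helps", {
  set.seed(1)
  model <- shallowANN(1, 1, seed = 3)
  x <- matrix(0.8); target <- 0.3
  g <- evomorbid:::annGradient(model, x, target)
  loss <- function(m) (annForward(m, x) - target)^2
  eps <- 1e-6
  for (slot in c("wIn", "thetaHidden", "wOut", "thetaOut")) {
    mp <- model; mm <- model
    slot(mp, slot) <- slot(model, slot) + eps
    slot(mm, slot) <- slot(model, slot) - eps
    fd <- (loss(mp) - loss(mm)) / (2 * eps)
    expect_equal(as.numeric(g[[slot]]), fd, tolerance = 1e-5)
  }
  # lr = 0 leaves the network unchanged
  toy <- toyPairs(40, 2)
  m0 <- annTrainBackprop(toy$x, toy$y, m = 3, epochs = 2, lr = 0, seed = 4)
  init <- shallowANN(2, 3, seed = evomorbid:::subSeed(4, 1), yMean = mean(toy$y))
  expect_equal(m0@wIn, init@wIn)
  # learnable toy: training reduces the RMSE
  m1 <- annTrainBackprop(toy$x, toy$y, m = 4, epochs = 25, lr = 0.2, seed = 4)
  hist <- attr(m1, "rmseHistory")
  init1 <- shallowANN(2, 4, seed = evomorbid:::subSeed(4, 1), yMean = mean(toy$y))
  expect_lt(min(hist), rmse(annForward(init1, toy$x), toy$y))
})

test_that("RBM energy matches the closed forms", {
  zero <- new("RBMLayer", w = matrix(0, 2, 2), b = c(0, 0), c = c(0, 0),
              visibleKind = "bernoulli")
  expect_equal(rbmEnergy(zero, c(0, 0), c(0, 0)), 0)
  one <- new("RBMLayer", w = matrix(0.2), b = 0.5, c = 0.3,
             visibleKind = "bernoulli")
  expect_equal(rbmEnergy(one, 1, 1), -1.0)
  # random 4 x 3 case vs term-by-term summation oracle
  set.seed(21)
  ly <- new("RBMLayer", w = matrix(rnorm(12), 4, 3), b = rnorm(4),
            c = rnorm(3), visibleKind = "bernoulli")
  x <- rnorm(4); z <- sample(0:1, 3, TRUE)
  oracle <- -sum(ly@b * x) - sum(ly@c * z) -
    sum(outer(x, z) * ly@w)
  expect_equal(rbmEnergy(ly, x, z), oracle, tolerance = 1e-12)
  lyG <- new("RBMLayer", w = ly@w, b = ly@b, c = ly@c,
             visibleKind = "gaussian")
  oracleG <- sum((x - ly@b)^2) / 2 - sum(ly@c * z) - sum(outer(x, z) * ly@w)
  expect_equal(rbmEnergy(lyG, x, z), oracleG, tolerance = 1e-12)
})

test_that("contrastive divergence follows the CD-1 update", {
  ly <- rbmLayer(1, 1, "bernoulli", seed = 2)
  # lr = 0: parameters unchanged, error still reported
  set.seed(5)
  st0 <- rbmCDStep(ly, matrix(1), lr = 0)
  expect_identical(st0$layer@w, ly@w)
  expect_gte(st0$reconError, 0)
  # hand-derived CD-1 on a 1 x 1 layer with a replayed hidden draw
  x <- matrix(1)
  set.seed(77); u <- runif(1)
  h0p <- sigmoid(1 * ly@w[1, 1] + ly@c)
  h0 <- as.numeric(u < h0p)
  v1 <- sigmoid(ly@b + ly@w[1, 1] * h0)
  h1p <- sigmoid(v1 * ly@w[1, 1] + ly@c)
  set.seed(77)
  st <- rbmCDStep(ly, x, lr = 0.5)
  expect_equal(st$layer@w[1, 1], ly@w[1, 1] + 0.5 * (1 * h0p - v1 * h1p),
               tolerance = 1e-12)
  expect_equal(st$layer@b, ly@b + 0.5 * (1 - v1), tolerance = 1e-12)
  expect_equal(st$layer@c, ly@c + 0.5 * (h0p - h1p), tolerance = 1e-12)
})

test_that("CD training reduces reconstruction error on a two-mode toy", {
  set.seed(8)
  modes <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  X <- modes[sample(1:2, 100, TRUE), ] +
    matrix(rbinom(600, 1, 0.05), 100, 6)
  X <- pmin(X, 1)
  ly <- rbmLayer(6, 3, "bernoulli", seed = 1)
  err0 <- rbmReconError(ly, X)
  set.seed(10)
  for (ep in 1:20) ly <- rbmCDStep(ly, X, lr = 0.3)$layer
  expect_lt(rbmReconError(ly, X), err0)
})

test_that("autoencoder mappings and losses match hand evaluation", {
  z0 <- autoencoderLayer(3, 2, seed = 1)
  z0@w[] <- 0; z0@b[] <- 0
  expect_equal(as.numeric(aeEncode(z0, c(1, 2, 3))), c(0.5, 0.5))
  # hand-set 2 <-> 1 layer
  ly <- new("AutoencoderLayer", w = matrix(c(0.5, -0.3), 1, 2), b = 0.1,
            wp = matrix(c(0.8, 0.2), 2, 1), bp = c(-0.1, 0.3), rho = 0)
  x <- c(0.4, 0.9)
  z <- 1 / (1 + exp(-(0.5 * 0.4 - 0.3 * 0.9 + 0.1)))
  xp <- 1 / (1 + exp(-(c(0.8, 0.2) * z + c(-0.1, 0.3))))
  expect_equal(as.numeric(aeEncode(ly, x)), z, tolerance = 1e-14)
  expect_equal(as.numeric(aeDecode(ly, z)), xp, tolerance = 1e-14)
  expect_equal(aeReconstructionLoss(ly, matrix(x, 1)), sum((x - xp)^2),
               tolerance = 1e-12)
  # direct norm example: x' = x + (0.1, 0) -> loss 0.01
  expect_equal(sum((c(0.3, 0.5) - c(0.4, 0.5))^2), 0.01)
  # random batch vs explicit loop oracle
  set.seed(30)
  lyr <- autoencoderLayer(5, 3, seed = 2)
  X <- matrix(runif(40), 8, 5)
  loop <- mean(vapply(1:8, function(i) {
    xi <- X[i, ]
    zi <- sigmoid(as.numeric(lyr@w %*% xi) + lyr@b)
    xpi <- sigmoid(as.numeric(lyr@wp %*% zi) + lyr@bp)
    sum((xi - xpi)^2)
  }, numeric(1)))
  expect_equal(aeReconstructionLoss(lyr, X), loop, tolerance = 1e-12)
  # outputs elementwise in (0, 1)
  out <- aeDecode(lyr, aeEncode(lyr, matrix(rnorm(50), 10, 5)))
  expect_true(all(out > 0 & out < 1))
})

test_that("masking corruption zeroes the configured fraction", {
  x <- c(1.5, -2, 3, 0.5)
  expect_identical(corruptInput(x, 0), x)
  expect_equal(corruptInput(x, 0.5, mask = c(TRUE, FALSE, TRUE, FALSE)),
               c(0, -2, 0, 0.5))
  set.seed(14)
  zeroed <- replicate(2000, sum(corruptInput(rep(1, 50), 0.2) == 0))
  phat <- mean(zeroed) / 50
  expect_lt(abs(phat - 0.2), 3 * sqrt(0.2 * 0.8 / (2000 * 50)))
  expect_error(corruptInput(x, 1), "rho")
})

test_that("corruption at rate zero consumes no random numbers", {
  x <- as.numeric(1:10)
  set.seed(3); s0 <- .Random.seed
  invisible(corruptInput(x, 0))
  expect_identical(.Random.seed, s0)    # stream untouched at rho = 0
  invisible(corruptInput(x, 0.3))
  expect_false(identical(.Random.seed, s0))
})

test_that("the K = 1 mixture head equals conditional-Gaussian regression", {
  set.seed(44)
  z <- matrix(rnorm(300), 100, 3)
  y <- 0.3 * z[, 1] - 0.1 * z[, 3] + rnorm(100, 0, 0.05)
  headK1 <- gmmFitJoint(z, y, K = 1, seed = 1)
  # closed-form conditional mean from joint moments (same regularization)
  M <- cbind(z, y)
  mu <- colMeans(M)
  S <- crossprod(sweep(M, 2, mu)) / 100 + diag(1e-6, 4)
  A <- solve(S[1:3, 1:3], S[1:3, 4])
  znew <- matrix(rnorm(30), 10, 3)
  oracle <- mu[4] + as.numeric(sweep(znew, 2, mu[1:3]) %*% A)
  expect_equal(gmmPredict(headK1, znew), oracle, tolerance = 1e-8)
  # and agrees with ordinary least squares up to the tiny regularization
  fit <- lm(y ~ z)
  expect_equal(gmmPredict(headK1, znew),
               as.numeric(cbind(1, znew) %*% coef(fit)), tolerance = 1e-4)
})

test_that("zero cross-covariance collapses prediction to the marginal mean", {
  z <- matrix(c(-1, 1, -1, 1), 4, 1)
  y <- c(0.2, 0.2, 0.8, 0.8)       # exactly uncorrelated with z
  head1 <- gmmFitJoint(z, y, K = 1, seed = 1)
  expect_equal(gmmPredict(head1, matrix(c(-2, 0, 3), 3, 1)),
               rep(mean(y), 3), tolerance = 1e-8)
})

test_that("EM log-likelihood is non-decreasing on separated mixtures", {
  for (s in 1:5) {
    set.seed(s)
    z <- rbind(matrix(rnorm(60, -2, 0.3), 30, 2),
               matrix(rnorm(60, 2, 0.3), 30, 2))
    y <- c(rnorm(30, 0.2, 0.02), rnorm(30, 0.8, 0.02))
    h <- gmmFitJoint(z, y, K = 2, seed = s)
    ll <- attr(h, "logLik")
    expect_true(all(diff(ll) >= -1e-6))
    expect_equal(sum(h@weights), 1, tolerance = 1e-12)
  }
  expect_error(gmmFitJoint(matrix(rnorm(4), 2, 2), c(0.1, 0.2), K = 5),
               "K <= number")
})

test_that("mixture fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")   # Mclust needs its namespace attached
  set.seed(55)
  z <- c(rnorm(60, -2, 0.4), rnorm(60, 2, 0.4))
  y <- c(rnorm(60, 0.2, 0.05), rnorm(60, 0.7, 0.05))
  h <- gmmFitJoint(matrix(z), y, K = 2, seed = 2)
  mc <- mclust::Mclust(cbind(z, y), G = 2, modelNames = "VVV",
                       verbose = FALSE)
  # same solution up to component relabelling
  ord <- order(h@means[, 1]); ordMc <- order(mc$parameters$mean[1, ])
  expect_equal(h@means[ord, 1], unname(mc$parameters$mean[1, ordMc]),
               tolerance = 0.05)
  expect_equal(sort(h@weights), sort(mc$parameters$pro), tolerance = 0.05)
})

test_that("flatten and restore are exact inverses for every model kind", {
  ann <- shallowANN(5, 3, seed = 6)
  v <- flattenParams(ann)
  expect_equal(nParams(ann), 5 * 3 + 3 + 3 + 1)
  expect_equal(flattenParams(restoreParams(ann, v)), v)
  ann2 <- restoreParams(ann, rev(v))
  expect_equal(flattenParams(ann2), rev(v))

  for (kind in c("DBN", "DAE", "DDAE")) {
    st <- deepStack(kind, 7L, c(4L, 3L, 2L), rho = 0.2, seed = 2)
    v <- flattenParams(st)
    expect_equal(length(v), nParams(st))
    st2 <- restoreParams(st, v)
    expect_identical(flattenParams(st2), v)
    # counting formula per layer chain
    sizes <- c(7L, 4L, 3L, 2L)
    expected <- if (kind == "DBN") {
      sum(sizes[-4] + sizes[-1] + sizes[-4] * sizes[-1])
    } else {
      sum(2 * sizes[-4] * sizes[-1] + sizes[-4] + sizes[-1])
    }
    expect_equal(nParams(st), expected)
  }
  expect_error(restoreParams(ann, 1:3), "mismatch")
})
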