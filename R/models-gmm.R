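## log density of rows of M under one multivariate Gaussian (via Cholesky)
.mvnLogDensity <- function(M, mean, sigma) {
  d <- ncol(M)
  ch <- chol(sigma)
  cen <- sweep(M, 2L, mean, "-")
  q <- backsolve(ch, t(cen), transpose = TRUE)   # d x N
  -0.5 * colSums(q^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

#' Fit a Gaussian-mixture output head over (codes, morbidity)
#'
#' Expectation-maximization on the joint vectors `(z, y)` with K full
#' covariance components, a small diagonal regularization added at every
#' M-step, and k-means initialization (seeded). The log-likelihood is
#' non-decreasing across iterations; if the tolerance is not reached within
#' `maxIter` iterations a warning is raised and the best-so-far fit
#' returned.
#'
#' @param z numeric matrix of top-layer codes (rows = tuples) or vector.
#' @param y morbidity targets.
#' @param K number of components (default 3).
#' @param seed integer seed for the initialization.
#' @param maxIter,tol EM stopping rule: iterate until the relative
#'   log-likelihood change falls below `tol` (or `maxIter` is hit).
#' @param reg diagonal covariance regularization.
#' @return a [GMMHead-class]; attribute `"logLik"` holds the per-iteration
#'   log-likelihood trace.
#' @export
gmmFitJoint <- function(z, y, K = 3L, seed = 1L, maxIter = 200L, tol = 1e-6,
                        reg = 1e-6) {
  z <- as.matrix(z)
  M <- unname(cbind(z, y))
  N <- nrow(M); d1 <- ncol(M)
  stopIfNot(length(y) == N, "z and y lengths differ")
  stopIfNot(K >= 1L && K <= N, "need 1 <= K <= number of samples")
  resp <- withSeed(seed, {
    if (K == 1L) matrix(1, N, 1L) else {
      ## k-means assignment as a hard initial responsibility; jitter ties
      cl <- tryCatch(kmeans(M, centers = K, nstart = 3L)$cluster,
                     error = function(e) sample.int(K, N, replace = TRUE))
      r <- matrix(0, N, K); r[cbind(seq_len(N), cl)] <- 1
      r
    }
  })
  ll <- numeric(0)
  head <- NULL
  for (it in seq_len(maxIter)) {
    ## M-step
    nk <- pmax(colSums(resp), 1e-10)
    wts <- nk / N
    means <- t(crossprod(resp, M) / nk)            # d1 x K
    covs <- array(0, c(d1, d1, K))
    for (k in seq_len(K)) {
      cen <- sweep(M, 2L, means[, k], "-")
      covs[, , k] <- crossprod(cen * resp[, k], cen) / nk[k] + diag(reg, d1)
    }
    head <- new("GMMHead", weights = wts / sum(wts), means = t(means),
                covariances = covs, zDim = as.integer(d1 - 1L))
    ## E-step
    logd <- vapply(seq_len(K), function(k)
      .mvnLogDensity(M, means[, k], covs[, , k]) + log(head@weights[k]),
      numeric(N))
    logd <- rbind(logd)
    if (N == 1L) logd <- matrix(logd, 1L, K)
    mx <- apply(logd, 1L, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- c(ll, sum(lse))
    resp <- exp(logd - lse)
    if (it > 1L &&
        abs(ll[it] - ll[it - 1L]) < tol * (1 + abs(ll[it]))) break
  }
  if (length(ll) == maxIter && maxIter > 1L &&
      abs(ll[maxIter] - ll[maxIter - 1L]) >= tol * (1 + abs(ll[maxIter])))
    warning("EM did not converge within maxIter; returning best-so-far fit")
  attr(head, "logLik") <- ll
  head
}

## per-component conditional pieces, cached once per head
.gmmConditionals <- function(head) {
  d <- head@zDim
  K <- length(head@weights)
  lapply(seq_len(K), function(k) {
    S <- head@covariances[, , k]
    Szz <- S[seq_len(d), seq_len(d), drop = FALSE]
    Szy <- S[seq_len(d), d + 1L]
    SzzInv <- solve(Szz)
    list(muZ = head@means[k, seq_len(d)], muY = head@means[k, d + 1L],
         SzzInv = SzzInv, A = as.numeric(SzzInv %*% Szy), Szz = Szz)
  })
}

## responsibilities of z rows under the marginal mixture over z
.gmmRespZ <- function(head, Z, cond) {
  K <- length(head@weights)
  logd <- vapply(seq_len(K), function(k)
    .mvnLogDensity(Z, cond[[k]]$muZ, cond[[k]]$Szz) + log(head@weights[k]),
    numeric(nrow(Z)))
  logd <- matrix(logd, nrow(Z), K)
  mx <- do.call(pmax, lapply(seq_len(K), function(k) logd[, k]))
  exp(logd - (mx + log(rowSums(exp(logd - mx)))))
}

#' Conditional-expectation prediction from the mixture head
#'
#' `E[y | z]` under the fitted joint mixture: the responsibility-weighted sum
#' of the per-component linear-Gaussian conditional means
#' `muY_k + Szy_k' Szz_k^{-1} (z - muZ_k)`.
#'
#' @param head a [GMMHead-class].
#' @param z code vector or matrix (rows = tuples).
#' @return numeric predictions.
#' @export
gmmPredict <- function(head, z) {
  Z <- .rowmat(z)
  stopIfNot(ncol(Z) == head@zDim, "code dimension mismatch")
  cond <- .gmmConditionals(head)
  resp <- .gmmRespZ(head, Z, cond)
  mks <- vapply(seq_along(cond), function(k) {
    cen <- sweep(Z, 2L, cond[[k]]$muZ, "-")
    cond[[k]]$muY + as.numeric(cen %*% cond[[k]]$A)
  }, numeric(nrow(Z)))
  rowSums(resp * matrix(mks, nrow(Z)))
}

#' Gradient of the mixture prediction with respect to the code
#'
#' Analytic `d E[y|z] / dz` for a single code vector:
#' `sum_k r_k(z) (A_k + m_k(z) (g_k - sum_j r_j g_j))` with
#' `A_k = Szz_k^{-1} Szy_k`, `g_k = -Szz_k^{-1}(z - muZ_k)` the gradient of
#' the component's log density, and `r_k` the responsibilities. Needed to
#' back-propagate the squared prediction error through the encoder stack.
#'
#' @param head a [GMMHead-class].
#' @param z single code vector (or a matrix of codes, one row each).
#' @return numeric gradient of length `zDim` (or an N x `zDim` matrix).
#' @export
gmmPredictGrad <- function(head, z) {
  Z <- .rowmat(z)
  out <- .gmmGradBatch(head, Z)
  if (is.vector(z)) as.numeric(out) else out
}

## vectorized d E[y|z] / dz over rows of Z: N x d matrix
.gmmGradBatch <- function(head, Z) {
  cond <- .gmmConditionals(head)
  resp <- .gmmRespZ(head, Z, cond)
  K <- length(cond); d <- head@zDim; N <- nrow(Z)
  Glist <- vector("list", K); Mlist <- vector("list", K)
  gBar <- matrix(0, N, d)
  for (k in seq_len(K)) {
    cen <- sweep(Z, 2L, cond[[k]]$muZ, "-")
    Glist[[k]] <- -cen %*% cond[[k]]$SzzInv        # grad of log N_k(z)
    Mlist[[k]] <- cond[[k]]$muY + as.numeric(cen %*% cond[[k]]$A)
    gBar <- gBar + resp[, k] * Glist[[k]]
  }
  out <- matrix(0, N, d)
  for (k in seq_len(K)) {
    out <- out + resp[, k] *
      (matrix(cond[[k]]$A, N, d, byrow = TRUE) +
         Mlist[[k]] * (Glist[[k]] - gBar))
  }
  out
}

setMethod("show", "GMMHead", function(object) {
  cat("GMMHead:", length(object@weights), "components over",
      object@zDim, "code dims + morbidity\n")
})
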