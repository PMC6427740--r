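#' Water wave optimization configuration
#'
#' Constructor for [WWOConfig-class]. Each candidate solution ("wave")
#' carries a wavelength that shrinks multiplicatively with fitness rank, so
#' fit waves search locally while unfit waves explore; a new population best
#' triggers "breaking" into a few solitary waves along random dimensions.
#'
#' @param populationSize number of waves (>= 2).
#' @param alpha wavelength-reduction coefficient (> 1; default 1.0026).
#' @param epsilon tie guard added to numerator and denominator of the
#'   wavelength exponent so equal-fitness populations stay defined.
#' @param betaStart,betaEnd breaking coefficient, decayed linearly from
#'   `betaStart` to `betaEnd` over the evaluation budget.
#' @param kMax maximum number of solitary waves per breaking event
#'   (`NA` = min(12, D)).
#' @param hMax wave height: number of consecutive unimproved propagations a
#'   wave survives before refraction replaces it with a draw between its
#'   position and the current best (stagnation control of the canonical
#'   water-wave method).
#' @param lambdaInit initial wavelength (default 0.5).
#' @param budget objective evaluations allowed after the initial population.
#' @param recomputeFromInit if `TRUE`, each generation's wavelength is
#'   recomputed from `lambdaInit` instead of shrinking the previous value.
#' @return a [WWOConfig-class].
#' @export
wwoConfig <- function(populationSize = 10L, alpha = 1.0026, epsilon = 1e-12,
                      betaStart = 0.25, betaEnd = 0.001, kMax = NA_integer_,
                      hMax = 6L, lambdaInit = 0.5, budget = 5000L,
                      recomputeFromInit = FALSE) {
  new("WWOConfig", populationSize = as.integer(populationSize), alpha = alpha,
      epsilon = epsilon, betaStart = betaStart, betaEnd = betaEnd,
      kMax = as.integer(kMax), hMax = as.integer(hMax),
      lambdaInit = lambdaInit, budget = as.integer(budget),
      recomputeFromInit = recomputeFromInit)
}

setMethod("show", "WWOConfig", function(object) {
  cat(sprintf(paste0("WWOConfig: pop %d, alpha %.4f, lambdaInit %.3f, ",
                     "beta %.3f -> %.3f, budget %d evals\n"),
              object@populationSize, object@alpha, object@lambdaInit,
              object@betaStart, object@betaEnd, object@budget))
})

#' Wavelength update
#'
#' `lambda * alpha ^ (-(f - fMin + eps) / (fMax - fMin + eps))`: the fitter
#' the wave (larger f; fitness is maximized), the more negative the exponent
#' and the smaller the new wavelength. `eps` keeps the update defined when
#' the whole population has equal fitness.
#'
#' @param lambda current wavelength.
#' @param f the wave's fitness; `fMin`/`fMax` population extremes.
#' @param cfg a [WWOConfig-class] (for `alpha` and `epsilon`).
#' @return updated wavelength.
#' @export
updateWavelength <- function(lambda, f, fMin, fMax, cfg) {
  stopIfNot(all(f >= fMin - 1e-12) && all(f <= fMax + 1e-12),
            "need fMin <= f <= fMax")
  lambda * cfg@alpha ^ (-(f - fMin + cfg@epsilon) / (fMax - fMin + cfg@epsilon))
}

#' @rdname updateWavelength
#' @param fMin,fMax population minimum and maximum fitness.
NULL

#' Propagate a wave
#'
#' Offsets every component by `lambda * u_i * L_i` with `u_i` uniform on
#' (-1, 1) and `L_i = upper_i - lower_i`; components that leave the search
#' box are redrawn uniformly inside their range.
#'
#' @param position numeric current position.
#' @param lambda the wave's wavelength.
#' @param lower,upper per-dimension bounds.
#' @param u optional fixed draws on (-1, 1) replacing the random ones
#'   (testing hook).
#' @return the propagated position.
#' @export
propagateWave <- function(position, lambda, lower, upper, u = NULL) {
  L <- upper - lower
  if (is.null(u)) u <- runif(length(position), -1, 1)
  out <- position + lambda * u * L
  bad <- out < lower | out > upper
  if (any(bad))
    out[bad] <- lower[bad] + runif(sum(bad)) * L[bad]
  out
}

#' Break the best wave into solitary waves
#'
#' Draws k uniform in 1..min(kMax, D) distinct dimensions; each solitary
#' wave shifts one of them by `N(0,1) * beta * L_i`. All candidates are
#' evaluated and the best of {input, solitary waves} is returned, so
#' breaking never loses fitness.
#'
#' @param best list with `position` and `fitness` of the current best wave.
#' @param objective fitness function (maximized).
#' @param beta current breaking coefficient.
#' @param lower,upper bounds.
#' @param kMax maximum solitary waves.
#' @param dims,draws optional fixed dimensions / normal draws (testing hook).
#' @return list: `position`, `fitness`, `evals` (objective calls spent).
#' @export
breakWave <- function(best, objective, beta, lower, upper, kMax,
                      dims = NULL, draws = NULL) {
  D <- length(best$position)
  kTop <- max(1L, min(kMax, D))
  if (is.null(dims)) {
    k <- sample.int(kTop, 1L)
    dims <- if (D == 1L) rep(1L, k) else sample.int(D, k)
  }
  k <- length(dims)
  if (is.null(draws)) draws <- rnorm(k)
  L <- upper - lower
  pos <- best$position; fit <- best$fitness
  for (j in seq_len(k)) {
    i <- dims[j]
    cand <- best$position
    cand[i] <- cand[i] + draws[j] * beta * L[i]
    if (cand[i] < lower[i] || cand[i] > upper[i])
      cand[i] <- lower[i] + runif(1L) * L[i]
    f <- objective(cand)
    if (f > fit) { pos <- cand; fit <- f }
  }
  list(position = pos, fitness = fit, evals = k)
}

#' Run water wave optimization
#'
#' Maximizes `objective` over the box `[lower, upper]`. The population is
#' initialized uniformly with wavelength `lambdaInit`; each generation
#' updates wavelengths from the population fitness spread, propagates every
#' wave (a propagated wave replaces its parent only when fitter), and breaks
#' the population best whenever propagation improves it. A wave that fails
#' to improve for `hMax` consecutive propagations is refracted: replaced by
#' a normal draw centred midway between its position and the current best
#' (component sd = half their distance), which re-focuses stagnant waves on
#' the promising region. Runs until the post-initialization evaluation
#' budget is exhausted. Deterministic for a fixed seed; the best-so-far
#' fitness never decreases.
#'
#' @param objective function(position) -> finite fitness (larger is better).
#' @param lower,upper numeric bounds defining the dimension D.
#' @param cfg a [wwoConfig()].
#' @param seed integer seed.
#' @param init optional list of starting positions (recycled/truncated to the
#'   population size; remaining waves drawn uniformly).
#' @param onGeneration optional callback `function(bestPosition)` invoked at
#'   the end of every generation; lets callers of a moving objective (e.g.
#'   one with a periodically refit output head) update shared state between
#'   generations.
#' @return list: `par` best position, `value` best fitness, `evals` total
#'   objective calls, `history` data.frame (generation, evals, bestFitness,
#'   meanWavelength).
#' @export
wwoOptimize <- function(objective, lower, upper, cfg = wwoConfig(), seed = 1L,
                        init = NULL, onGeneration = NULL) {
  D <- length(lower)
  stopIfNot(length(upper) == D && all(lower < upper),
            "bounds must satisfy lower < upper componentwise")
  kMax <- if (is.na(cfg@kMax)) min(12L, D) else min(cfg@kMax, D)
  L <- upper - lower
  evalObj <- function(pos) {
    f <- objective(pos)
    if (!is.finite(f))
      stop("objective returned a non-finite value at position (",
           paste(signif(pos, 6), collapse = ", "), ")")
    f
  }
  withSeed(seed, {
    np <- cfg@populationSize
    pos <- matrix(runif(np * D), np, D)
    pos <- sweep(sweep(pos, 2L, L, "*"), 2L, lower, "+")
    if (!is.null(init)) {
      for (i in seq_len(min(length(init), np)))
        pos[i, ] <- pmin(upper, pmax(lower, init[[i]]))
    }
    fit <- apply(pos, 1L, evalObj)
    lambda <- rep(cfg@lambdaInit, np)
    height <- rep(cfg@hMax, np)
    evals <- 0L                       # post-initialization evaluations
    bestIdx <- which.max(fit)
    bestPos <- pos[bestIdx, ]; bestFit <- fit[bestIdx]
    gen <- 0L
    hist <- list()
    while (evals < cfg@budget) {
      gen <- gen + 1L
      fMin <- min(fit); fMax <- max(fit)
      lambda <- updateWavelength(
        if (cfg@recomputeFromInit) rep(cfg@lambdaInit, np) else lambda,
        fit, fMin, fMax, cfg)
      for (i in seq_len(np)) {
        if (evals >= cfg@budget) break
        cand <- propagateWave(pos[i, ], lambda[i], lower, upper)
        f <- evalObj(cand); evals <- evals + 1L
        if (f > fit[i]) {
          pos[i, ] <- cand; fit[i] <- f; height[i] <- cfg@hMax
          if (f > bestFit) {
            ## a propagation produced a new best: break it immediately
            bestPos <- cand; bestFit <- f; bestIdx <- i
            if (evals < cfg@budget) {
              beta <- cfg@betaStart +
                (cfg@betaEnd - cfg@betaStart) * min(1, evals / cfg@budget)
              br <- breakWave(list(position = bestPos, fitness = bestFit),
                              evalObj, beta, lower, upper, kMax)
              evals <- evals + br$evals
              if (br$fitness > bestFit) {
                bestPos <- br$position; bestFit <- br$fitness
                pos[i, ] <- br$position; fit[i] <- br$fitness
              }
            }
          }
        } else {
          height[i] <- height[i] - 1L
          if (height[i] <= 0L) {
            height[i] <- cfg@hMax
            if (fit[i] < bestFit && evals < cfg@budget) {
              ## refraction: redraw the stagnant wave between itself and
              ## the best; wavelength is carried over
              mu <- (bestPos + pos[i, ]) / 2
              sdv <- pmax(abs(bestPos - pos[i, ]) / 2, 1e-12)
              cand <- rnorm(D, mu, sdv)
              bad <- cand < lower | cand > upper
              if (any(bad))
                cand[bad] <- lower[bad] + runif(sum(bad)) * L[bad]
              f <- evalObj(cand); evals <- evals + 1L
              pos[i, ] <- cand; fit[i] <- f
              if (f > bestFit) {
                bestPos <- cand; bestFit <- f; bestIdx <- i
              }
            }
          }
        }
      }
      hist[[gen]] <- c(generation = gen, evals = evals,
                       bestFitness = bestFit, meanWavelength = mean(lambda))
      if (!is.null(onGeneration)) onGeneration(bestPos)
    }
    list(par = bestPos, value = bestFit, evals = evals + np,
         history = as.data.frame(do.call(rbind, hist)))
  })
}
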