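#' Root mean squared error
#'
#' `sqrt(mean((actual - expected)^2))` — the training and evaluation
#' objective of every model kind.
#'
#' @param actual model outputs.
#' @param expected labeled morbidity targets.
#' @return numeric(1).
#' @export
rmse <- function(actual, expected) {
  stopIfNot(length(actual) == length(expected), "length mismatch")
  stopIfNot(length(actual) > 0, "empty vectors")
  sqrt(mean((actual - expected)^2))
}

#' Prediction accuracy percentage
#'
#' `100 * max(0, 1 - sum(|actual - expected|) / sum(expected))`: the
#' complement of the total absolute relative error, clipped to `[0, 100]`.
#' Scale-invariant and robust to single zero targets; when every expected
#' value is zero the score is 100 for a perfect all-zero prediction and 0
#' otherwise. This is the package's declared accuracy definition for
#' comparing models on morbidity scales of different magnitudes.
#'
#' @param actual model outputs.
#' @param expected nonnegative morbidity targets.
#' @return numeric(1) in `[0, 100]`.
#' @export
accuracyPct <- function(actual, expected) {
  stopIfNot(length(actual) == length(expected), "length mismatch")
  stopIfNot(all(expected >= 0), "expected values must be nonnegative")
  tot <- sum(expected)
  if (tot == 0) return(if (all(actual == 0)) 100 else 0)
  100 * max(0, 1 - sum(abs(actual - expected)) / tot)
}

#' Cross-validated evaluation of one model kind
#'
#' Builds the lagged pairs for one disease, splits them into k random folds,
#' and for each fold: computes imputation and standardization statistics on
#' the training folds only, trains the model there, and scores RMSE and
#' accuracy on the held-out fold. Deterministic for a fixed seed.
#'
#' @param kind model kind (see [trainSpec()]).
#' @param x a [SurveillanceExperiment-class].
#' @param disease disease label.
#' @param lag lag in weeks.
#' @param k number of folds (default 5).
#' @param spec a [trainSpec()].
#' @param seed integer seed (fold split and per-fold training).
#' @return data.frame with one row per fold (`model`, `disease`, `lag`,
#'   `fold`, `nTest`, `rmse`, `accuracy`) plus attributes `meanRmse` and
#'   `meanAccuracy` (arithmetic means of the fold values).
#' @export
crossValidate <- function(kind, x, disease, lag, k = 5L, spec = trainSpec(),
                          seed = 1L) {
  pairs <- makeLaggedPairs(x, disease, lag)
  folds <- splitKfold(nPairs(pairs), k, seed = subSeed(seed, 7L))
  rows <- lapply(seq_len(k), function(fold) {
    test <- subsetPairs(pairs, folds == fold)
    train <- subsetPairs(pairs, folds != fold)
    prep <- preprocessPairs(train, test)
    sp <- spec
    sp$seed <- subSeed(seed, 100L + fold)
    model <- trainModel(kind, prep$train, spec = sp)
    pred <- predictMorbidity(model, prep$test@features)
    data.frame(model = kind, disease = disease, lag = lag, fold = fold,
               nTest = nPairs(test), rmse = rmse(pred, prep$test@y),
               accuracy = accuracyPct(pred, prep$test@y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "meanRmse") <- mean(out$rmse)
  attr(out, "meanAccuracy") <- mean(out$accuracy)
  out
}

#' Sweep the prediction lag over a range
#'
#' Runs [crossValidate()] for each lag and reports the mean CV RMSE curve
#' and the RMSE-minimizing lag (ties resolved to the smallest lag).
#'
#' @param kind model kind.
#' @param x a [SurveillanceExperiment-class].
#' @param disease disease label.
#' @param lags integer lags to try (default 1:8).
#' @param k folds per lag.
#' @param spec a [trainSpec()].
#' @param seed integer seed.
#' @return list: `curve` data.frame (lag, meanRmse, meanAccuracy),
#'   `bestLag`.
#' @export
lagSweep <- function(kind, x, disease, lags = 1:8, k = 5L,
                     spec = trainSpec(), seed = 1L) {
  rows <- lapply(lags, function(lag) {
    cv <- crossValidate(kind, x, disease, lag, k = k, spec = spec,
                        seed = subSeed(seed, lag))
    data.frame(lag = lag, meanRmse = attr(cv, "meanRmse"),
               meanAccuracy = attr(cv, "meanAccuracy"))
  })
  curve <- do.call(rbind, rows)
  best <- curve$lag[which.min(curve$meanRmse)]  # which.min takes first tie
  list(curve = curve, bestLag = best)
}

#' Compare model kinds across diseases
#'
#' Full cross-validated grid of the selected model kinds and diseases under
#' a per-disease lag policy. A lag of `NA` for a disease selects, per model,
#' the RMSE-minimizing lag by [lagSweep()] (the policy used for diseases
#' whose lag cannot be fixed a priori).
#'
#' @param x a [SurveillanceExperiment-class].
#' @param kinds character model kinds (default all eight).
#' @param diseaseSet diseases to evaluate (default all in `x`).
#' @param lags named integer vector of lags per disease (NA = per-model
#'   argmin over `sweepLags`).
#' @param sweepLags lags tried when a disease's lag is NA.
#' @param k folds.
#' @param spec a [trainSpec()].
#' @param seed integer seed.
#' @return data.frame with one row per (model, disease, fold); attribute
#'   `"summary"` holds the per-(model, disease) means and chosen lag.
#' @export
compareModels <- function(x, kinds = c("MLR", "ANN", "DBN", "EvoDBN", "DAE",
                                       "EvoDAE", "DDAE", "EvoDDAE"),
                          diseaseSet = diseases(x), lags = 1L,
                          sweepLags = 1:8, k = 5L, spec = trainSpec(),
                          seed = 1L) {
  if (is.null(names(lags)) && length(lags) == 1L)
    lags <- stats::setNames(rep(lags, length(diseaseSet)), diseaseSet)
  stopIfNot(all(diseaseSet %in% names(lags)),
            "lags must be named for every disease (NA = argmin policy)")
  rows <- list(); summ <- list()
  for (d in diseaseSet) {
    for (kind in kinds) {
      lag <- lags[[d]]
      if (is.na(lag))
        lag <- lagSweep(kind, x, d, lags = sweepLags, k = k, spec = spec,
                        seed = subSeed(seed, 17L))$bestLag
      cv <- crossValidate(kind, x, d, lag, k = k, spec = spec,
                          seed = subSeed(seed, 23L))
      rows[[paste(d, kind)]] <- cv
      summ[[paste(d, kind)]] <- data.frame(
        model = kind, disease = d, lag = lag,
        meanRmse = attr(cv, "meanRmse"),
        meanAccuracy = attr(cv, "meanAccuracy"), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "summary") <- do.call(rbind, c(summ, list(make.row.names = FALSE)))
  out
}

#' Plot an RMSE-versus-lag curve
#'
#' @param sweep result of [lagSweep()].
#' @param ... passed to [graphics::plot()].
#' @export
plotLagSweep <- function(sweep, ...) {
  graphics::plot(sweep$curve$lag, sweep$curve$meanRmse, type = "b",
                 xlab = "time lag (weeks)", ylab = "mean CV RMSE", ...)
  graphics::abline(v = sweep$bestLag, lty = 2, col = "grey40")
}

#' Bar plot of mean accuracy per model for one disease
#'
#' @param comparison result of [compareModels()].
#' @param disease disease to plot.
#' @param ... passed to [graphics::barplot()].
#' @export
plotAccuracyBars <- function(comparison, disease, ...) {
  s <- attr(comparison, "summary")
  s <- s[s$disease == disease, ]
  graphics::barplot(s$meanAccuracy, names.arg = s$model, las = 2,
                    ylab = "mean CV accuracy (%)", main = disease, ...)
}
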