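#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with R's random-number generator seeded at `seed`, then restores
#' whatever RNG state the caller had. All stochastic routines in the package
#' funnel their randomness through this helper so that a user-supplied seed
#' makes a whole pipeline reproducible without clobbering the session RNG.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a distinct sub-seed from a base seed for independent stages.
## Kept below 2^31 - 1 so the result is always a valid integer seed.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## coerce a vector to a one-row matrix without copying matrices
.rowmat <- function(x) if (is.matrix(x)) x else matrix(x, 1L, length(x))

## add a vector to every row of a matrix (fast sweep(M, 2, v, "+"))
.addCols <- function(M, v) M + rep(v, each = nrow(M))
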