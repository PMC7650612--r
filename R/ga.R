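#' @include AllClasses.R
NULL

#' Real-coded genetic algorithm over a log10-scaled box
#'
#' Global optimizer used for parameter estimation. The search runs in
#' log10 coordinates of the [SearchSpace-class] bounds (internally scaled
#' to the unit hypercube): bounds spanning two to three decades make
#' linear-scale crossover degenerate. Each generation draws `popSize`
#' children by blend (BLX-alpha) crossover between two distinct parents
#' drawn uniformly from the current population, then parents and children
#' compete for survival (mu+lambda replacement), which makes the
#' best-so-far history non-increasing by construction. As a diversity
#' floor, survivors that duplicate a better-ranked individual are re-seeded
#' uniformly from the prior, keeping the population spread without
#' distance bookkeeping.
#'
#' A fixed seed fully determines the run; the caller's RNG state is left
#' untouched.
#'
#' @param objective function mapping a named natural-scale parameter
#'   vector to a scalar; non-finite values mark infeasible candidates.
#' @param space a [SearchSpace-class].
#' @param config a [GAConfig-class]; `popSize` must be at least twice the
#'   search dimension.
#' @return list with `par` (best named vector, natural scale), `value`
#'   (its objective), `history` (best-so-far objective per generation),
#'   and `nEvaluations`.
#' @examples
#' sp <- searchSpace(c(a = 1, b = 1))
#' res <- gaOptimize(function(x) (x[["a"]] - 2)^2 + (x[["b"]] - 0.5)^2,
#'                   sp, gaConfig(popSize = 20, nGenerations = 30, seed = 1))
#' res$par
#' @export
gaOptimize <- function(objective, space, config) {
  stopifnot(is(space, "SearchSpace"), is(config, "GAConfig"))
  validObject(space); validObject(config)
  d <- length(space@name)
  if (config@popSize < 2 * d)
    stop(sprintf("popSize (%d) must be at least twice the search dimension (%d)",
                 as.integer(config@popSize), d), call. = FALSE)

  lo <- log10(space@lower)
  hi <- log10(space@upper)
  nm <- space@name
  decode <- function(u) setNames(10^(lo + u * (hi - lo)), nm)
  evalU <- function(u) {
    v <- objective(decode(u))
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) Inf else v
  }

  np <- as.integer(config@popSize)
  ng <- as.integer(config@nGenerations)
  alpha <- config@blxAlpha

  withSeed(config@seed, {
    pop <- matrix(runif(np * d), np, d)
    fit <- apply(pop, 1, evalU)
    nEval <- np
    if (all(!is.finite(fit)))
      stop("objective is non-finite on every initial individual; check the model and bounds",
           call. = FALSE)

    history <- numeric(0)
    best <- min(fit)
    sinceImprove <- 0L

    for (g in seq_len(ng)) {
      ## children by blend crossover
      children <- matrix(0, np, d)
      for (j in seq_len(np)) {
        pr <- sample.int(np, 2L)
        a <- pop[pr[1L], ]; b <- pop[pr[2L], ]
        cmin <- pmin(a, b); cmax <- pmax(a, b)
        spread <- cmax - cmin
        child <- runif(d, cmin - alpha * spread, cmax + alpha * spread)
        children[j, ] <- pmin(pmax(child, 0), 1)
      }
      cfit <- apply(children, 1, evalU)
      nEval <- nEval + np

      ## mu+lambda survival: parents compete with children
      all_pop <- rbind(pop, children)
      all_fit <- c(fit, cfit)
      ord <- order(all_fit)[seq_len(np)]
      pop <- all_pop[ord, , drop = FALSE]
      fit <- all_fit[ord]

      ## diversity floor: re-seed duplicates of better-ranked survivors.
      ## "duplicate" is judged at 1e-3 resolution of the unit box, so a
      ## collapsing population is actively re-spread while the elite (and
      ## near-elite children at distinct rounded coordinates) keep
      ## refining the optimum
      dup <- duplicated(round(pop, 3))
      ## never reseed the elite block
      if (config@nElite > 0)
        dup[seq_len(as.integer(config@nElite))] <- FALSE
      if (any(dup)) {
        k <- sum(dup)
        pop[dup, ] <- matrix(runif(k * d), k, d)
        fit[dup] <- apply(pop[dup, , drop = FALSE], 1, evalU)
        nEval <- nEval + k
      }

      newBest <- min(fit)
      if (newBest < best - .Machine$double.eps * abs(best)) {
        best <- newBest
        sinceImprove <- 0L
      } else sinceImprove <- sinceImprove + 1L
      best <- min(best, newBest)
      history <- c(history, best)
      if (is.finite(config@convergenceWindow) &&
          sinceImprove >= config@convergenceWindow) break
    }

    ib <- which.min(fit)
    list(par = decode(pop[ib, ]), value = fit[ib], history = history,
         nEvaluations = nEval)
  })
}
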