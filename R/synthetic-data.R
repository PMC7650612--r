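#' @include AllClasses.R mini-erbb.R expression.R
NULL

.SYNTH_TIMES <- c(0, 5, 15, 30, 45, 60, 90, 120)

#' Generate synthetic cell lines for the reduced ErbB model
#'
#' Emulates the study design used for model individualization: several
#' "cell lines" that share one set of kinetic parameters and differ only
#' in their expression-derived initial amounts. Per line, each fixture
#' gene's TPM is drawn log-uniformly over `tpmRange`; the line is then
#' simulated under an EGF-like and an HRG-like 10 nM stimulus with the
#' fixture's true parameters, the observables (pAkt, pERK, pc-Fos) are
#' sampled at sparse time points, multiplicative lognormal noise with the
#' given coefficient of variation is applied (Western-blot-like;
#' observables stay non-negative), and values are normalized per
#' observable to a pooled maximum of 1 within each line.
#'
#' A fixed seed makes the output fully reproducible, including the files
#' written by [cliGenerateData()].
#'
#' @param nLines number of cell lines (>= 2: training plus held-out).
#' @param seed RNG seed.
#' @param noiseCv coefficient of variation of the multiplicative noise
#'   (0 disables noise).
#' @param tpmRange range of the log-uniform TPM draw (default 10-500).
#' @param times sampling times in minutes.
#' @param doses ligand dose (nM) applied in each single-ligand condition.
#' @return list of class `sigdyn_synthetic` with elements:
#'   `expression` ([ExpressionTable-class]), `measurements` (named list,
#'   line -> data.frame observable/condition/time_min/value/stderr),
#'   `noiseless` (same shape, noise-free normalized truth), `truth`
#'   (fixture kinetics + weights), `mapping`, `lineNames`, `times`,
#'   `noiseCv`, `seed`, `conditions`.
#' @examples
#' s <- generateSyntheticCellLines(nLines = 2, seed = 1, noiseCv = 0)
#' names(s$measurements)
#' @export
generateSyntheticCellLines <- function(nLines = 4, seed = 1, noiseCv = 0.1,
                                       tpmRange = c(10, 500),
                                       times = .SYNTH_TIMES,
                                       doses = 10) {
  if (nLines < 2)
    stop("nLines must be at least 2 (training plus held-out)", call. = FALSE)
  if (noiseCv < 0) stop("noiseCv must be non-negative", call. = FALSE)

  model <- miniErbBModel()
  truth <- miniErbBTruth()
  mapping <- geneMapping(truth$geneFamilies)
  genes <- unlist(truth$geneFamilies, use.names = FALSE)
  lineNames <- sprintf("CL%02d", seq_len(nLines))

  conditions <- list(
    EGF = simulationCondition(c(EGF = doses, HRG = 0),
                              duration = max(times), timeGrid = times),
    HRG = simulationCondition(c(EGF = 0, HRG = doses),
                              duration = max(times), timeGrid = times))

  withSeed(seed, {
    tpm <- matrix(10^runif(length(genes) * nLines,
                           log10(tpmRange[1]), log10(tpmRange[2])),
                  nrow = length(genes), ncol = nLines,
                  dimnames = list(genes, lineNames))
    expr <- expressionTable(tpm)
    sigma <- if (noiseCv > 0) sqrt(log(1 + noiseCv^2)) else 0

    measurements <- list()
    noiseless <- list()
    for (ln in lineNames) {
      raw <- simulateLineRaw(model, truth$kinetics, truth$weights,
                             expr, mapping, ln, conditions)
      clean <- tracesToDataFrame(normalizeTraces(raw))
      clean$stderr <- 0
      noiseless[[ln]] <- clean

      noisy <- raw
      if (sigma > 0) {
        noisy@traces <- lapply(raw@traces, function(m) {
          eps <- matrix(rlnorm(length(m), meanlog = -sigma^2 / 2,
                               sdlog = sigma), nrow(m), ncol(m))
          m2 <- m * eps
          dimnames(m2) <- dimnames(m)
          m2
        })
      }
      df <- tracesToDataFrame(normalizeTraces(noisy))
      df$stderr <- if (noiseCv > 0) noiseCv * df$value else 0
      measurements[[ln]] <- df
    }
    structure(list(expression = expr, measurements = measurements,
                   noiseless = noiseless, truth = truth,
                   mapping = mapping, lineNames = lineNames,
                   times = times, noiseCv = noiseCv, seed = seed,
                   conditions = conditions),
              class = "sigdyn_synthetic")
  })
}

## Simulate one cell line under all conditions with given kinetics/weights;
## returns raw ObservableTraces. Used by the generator, the objective and
## prediction.
simulateLineRaw <- function(model, kinetics, weights, expr, mapping,
                            cellLine, conditions,
                            rtol = .RTOL_DEFAULT, atol = .ATOL_DEFAULT) {
  tpm <- extractGenes(expr, mapping, cellLine)
  ib <- buildInitialValues(tpm, weights, model, .padTotals(model, kinetics))
  trajs <- lapply(conditions, function(cond)
    simulateCondition(model, ib$params, ib$state, cond,
                      rtol = rtol, atol = atol))
  if (!all(vapply(trajs, function(t) t@success, logical(1))))
    stop("integration failed for cell line ", cellLine, call. = FALSE)
  computeObservables(model, trajs)
}

## Complete a kinetics-only vector with placeholder totals so it covers the
## model's full parameter order; totals are overwritten by initialBuilder.
.padTotals <- function(model, kinetics) {
  pn <- model@parameterNames
  out <- setNames(numeric(length(pn)), pn)
  out[names(kinetics)] <- kinetics
  out
}

#' Write a synthetic cell-line set to disk
#'
#' Emits the expression table in the CCLE-like TSV dialect
#' (`expression.tsv`), one measurement TSV per line
#' (`measurements_<line>.tsv` with columns observable, condition,
#' time_min, value, stderr), and a `manifest.yaml` recording the seed,
#' noise level, sampling times and line roles (the last line is held out,
#' the rest are training, mirroring a train-on-3/predict-1 design).
#'
#' @param x a `sigdyn_synthetic` object from
#'   [generateSyntheticCellLines()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticCellLines <- function(x, dir) {
  stopifnot(inherits(x, "sigdyn_synthetic"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  writeExpressionTable(x$expression, file.path(dir, "expression.tsv"),
                       dialect = "ccle")
  for (ln in x$lineNames)
    writeTsv(x$measurements[[ln]],
             file.path(dir, sprintf("measurements_%s.tsv", ln)))
  n <- length(x$lineNames)
  manifest <- list(
    seed = x$seed, noise_cv = x$noiseCv,
    times_min = x$times,
    training_lines = x$lineNames[-n],
    heldout_lines = x$lineNames[n])
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
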