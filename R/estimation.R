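#' @include AllClasses.R model-core.R expression.R synthetic-data.R
NULL

#' Build a SearchSpace from reference kinetics and weighted species
#'
#' Kinetic constants are searched within 0.1 to 10 times their reference
#' values; weighting factors within the absolute range 0.1 to 100
#' (reference 1). The optimizer works in log10 coordinates of these boxes.
#'
#' @param kineticRef named numeric, reference values of the searched
#'   kinetic constants (strictly positive).
#' @param weightSpecies character, species whose weighting factors are
#'   searched; their names enter the space as `w_<species>`.
#' @return a [SearchSpace-class].
#' @examples
#' searchSpace(c(ka1 = 0.03, kerk = 0.005), c("ERK", "Akt"))
#' @export
searchSpace <- function(kineticRef = numeric(), weightSpecies = character()) {
  if (length(kineticRef)) {
    checkNamedNumeric(kineticRef, "kineticRef")
    if (any(kineticRef <= 0))
      stop("kinetic reference values must be strictly positive",
           call. = FALSE)
  }
  wn <- if (length(weightSpecies)) paste0("w_", weightSpecies) else character()
  new("SearchSpace",
      name = c(names(kineticRef), wn),
      reference = c(unname(kineticRef), rep(1, length(wn))),
      lower = c(unname(kineticRef) * 0.1, rep(.WEIGHT_LOWER, length(wn))),
      upper = c(unname(kineticRef) * 10, rep(.WEIGHT_UPPER, length(wn))),
      isWeight = c(rep(FALSE, length(kineticRef)), rep(TRUE, length(wn))))
}

#' Assemble a FitProblem from expression data and measurement tables
#'
#' @param model a [ReactionModel-class].
#' @param expression an [ExpressionTable-class].
#' @param mapping a [GeneMapping-class] for the model's
#'   expression-initialized species.
#' @param measurements named list, cell line -> long data.frame with
#'   columns observable, condition, time_min, value (normalized to
#'   `[0, 1]`); an optional stderr column is carried but not used by the
#'   objective.
#' @param trainLines cell-line ids to train on.
#' @param conditions named list of [SimulationCondition-class]; all must
#'   share one time grid covering the measurement times.
#' @param space a [SearchSpace-class].
#' @param fixedKinetics full named kinetic vector supplying values for
#'   constants not in the search space.
#' @param fixedWeights named weighting factors for expression species not
#'   in the search space (default 1 for each).
#' @return a [FitProblem-class].
#' @export
fitProblem <- function(model, expression, mapping, measurements,
                       trainLines, conditions, space, fixedKinetics,
                       fixedWeights = NULL) {
  stopifnot(is(model, "ReactionModel"), is(expression, "ExpressionTable"),
            is(mapping, "GeneMapping"), is(space, "SearchSpace"))
  grid <- conditions[[1]]@timeGrid
  for (cond in conditions)
    if (!identical(cond@timeGrid, grid))
      stop("all conditions must share one time grid", call. = FALSE)

  if (is.null(fixedWeights))
    fixedWeights <- setNames(rep(1, length(model@expressionSpecies)),
                             model@expressionSpecies)

  lines <- lapply(trainLines, function(ln) {
    if (!ln %in% names(measurements))
      stop("no measurements for training line ", ln, call. = FALSE)
    df <- measurements[[ln]]
    need <- c("observable", "condition", "time_min", "value")
    if (!all(need %in% names(df)))
      stop("measurement table must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    meas <- lapply(observableNames(model), function(ob) {
      m <- matrix(NA_real_, length(grid), length(conditions),
                  dimnames = list(NULL, names(conditions)))
      sub <- df[df$observable == ob, , drop = FALSE]
      for (k in seq_len(nrow(sub))) {
        i <- match(sub$time_min[k], grid)
        j <- match(sub$condition[k], names(conditions))
        if (is.na(i))
          stop(sprintf("line %s: measurement time %g not on the simulation grid",
                       ln, sub$time_min[k]), call. = FALSE)
        if (is.na(j))
          stop(sprintf("line %s: unknown condition '%s'", ln,
                       sub$condition[k]), call. = FALSE)
        m[i, j] <- sub$value[k]
      }
      m
    })
    names(meas) <- observableNames(model)
    list(tpm = extractGenes(expression, mapping, ln), meas = meas)
  })
  names(lines) <- trainLines

  new("FitProblem", model = model, lines = lines, conditions = conditions,
      space = space, fixedKinetics = .fullKinetics(model, fixedKinetics),
      fixedWeights = fixedWeights, timeGrid = grid)
}

.fullKinetics <- function(model, kinetics) {
  totals <- model@parameterNames[grepl("tot$", model@parameterNames)]
  need <- setdiff(model@parameterNames, totals)
  missing <- setdiff(need, names(kinetics))
  if (length(missing))
    stop("fixedKinetics is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  kinetics[need]
}

## Split a candidate vector into kinetics overrides and weight overrides.
.splitCandidate <- function(candidate, space) {
  isW <- space@isWeight[match(names(candidate), space@name)]
  list(kinetics = candidate[!isW],
       weights = setNames(candidate[isW],
                          sub("^w_", "", names(candidate)[isW])))
}

#' Residual sum of squares of a candidate over the training set
#'
#' For each training cell line, initial amounts are built from the line's
#' summed TPM and the candidate's weighting factors, both conditions are
#' simulated, observables are computed and normalized with the pooled
#' per-line convention, and squared differences to the normalized
#' measurements are summed over lines, observables, conditions and
#' measured time points. Any integration failure maps the candidate to
#' `+Inf` (failure is data, not an exception).
#'
#' The objective decomposes over cell lines and is invariant to their
#' order.
#'
#' @param candidate named numeric vector over the search-space names
#'   (natural scale).
#' @param problem a [FitProblem-class].
#' @param perLine return the per-line decomposition instead of the total.
#' @return scalar RSS (or named per-line vector when `perLine = TRUE`).
#' @export
objectiveRSS <- function(candidate, problem, perLine = FALSE) {
  stopifnot(is(problem, "FitProblem"))
  checkNamedNumeric(candidate, "candidate")
  unknown <- setdiff(names(candidate), problem@space@name)
  if (length(unknown))
    stop("candidate has entries outside the search space: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  parts <- .splitCandidate(candidate, problem@space)
  kinetics <- problem@fixedKinetics
  kinetics[names(parts$kinetics)] <- parts$kinetics
  weights <- problem@fixedWeights
  weights[names(parts$weights)] <- parts$weights
  model <- problem@model

  rssLine <- vapply(names(problem@lines), function(ln) {
    l <- problem@lines[[ln]]
    ib <- tryCatch(
      buildInitialValues(l$tpm[model@expressionSpecies], weights, model,
                         .padTotals(model, kinetics)),
      error = function(e) NULL)
    if (is.null(ib)) return(Inf)
    trajs <- lapply(problem@conditions, function(cond)
      simulateCondition(model, ib$params, ib$state, cond))
    if (!all(vapply(trajs, function(t) t@success, logical(1))))
      return(Inf)
    sim <- normalizeTraces(computeObservables(model, trajs))
    tot <- 0
    for (ob in names(l$meas)) {
      d <- l$meas[[ob]] - sim@traces[[ob]]
      tot <- tot + sum(d^2, na.rm = TRUE)
    }
    tot
  }, numeric(1))

  if (perLine) rssLine else sum(rssLine)
}

#' Run repeated GA optimizations and collect an ensemble
#'
#' Launches `nRuns` independent genetic-algorithm runs with per-run seeds
#' `config seed + run index`, then accepts every run whose final objective
#' is at or below the acceptance threshold. When no threshold is given it
#' defaults to 1.5 times the best objective found across all runs
#' ("good-fitting" relative to the best run). Runs are independent, so
#' results do not depend on execution order.
#'
#' @param problem a [FitProblem-class].
#' @param config a [GAConfig-class]; its seed acts as the base seed.
#' @param nRuns number of optimization runs (default 30).
#' @param acceptanceThreshold objective cutoff for membership (default
#'   `NULL` = 1.5 x best).
#' @param verbose print per-run progress.
#' @return an [Ensemble-class].
#' @export
runEnsemble <- function(problem, config, nRuns = 30,
                        acceptanceThreshold = NULL, verbose = FALSE) {
  stopifnot(is(problem, "FitProblem"), is(config, "GAConfig"), nRuns >= 1)
  runs <- vector("list", nRuns)
  for (i in seq_len(nRuns)) {
    cfg <- config
    cfg@seed <- config@seed + i
    res <- gaOptimize(function(x) objectiveRSS(x, problem),
                      problem@space, cfg)
    runs[[i]] <- list(params = res$par, objective = res$value,
                      seed = cfg@seed, history = res$history)
    if (verbose)
      message(sprintf("run %d/%d: objective %.6g", i, nRuns, res$value))
  }
  finals <- vapply(runs, `[[`, numeric(1), "objective")
  threshold <- acceptanceThreshold %||% (1.5 * min(finals))
  keep <- which(is.finite(finals) & finals <= threshold)
  if (!length(keep))
    stop(sprintf("empty ensemble: no run reached threshold %.6g (best rejected objective: %.6g)",
                 threshold, min(finals)), call. = FALSE)
  members <- lapply(runs[keep], function(r)
    r[c("params", "objective", "seed")])
  new("Ensemble", members = members,
      metadata = list(baseSeed = config@seed, nRuns = nRuns,
                      threshold = threshold, allObjectives = finals,
                      histories = lapply(runs, `[[`, "history")),
      problem = problem)
}

#' Predict an untrained cell line from the ensemble
#'
#' For each ensemble member, initial amounts for the *new* cell line are
#' built from its expression profile using that member's weighting
#' factors, the model is simulated under the training conditions with the
#' member's kinetics, and the observables are normalized per line. The
#' prediction is the pointwise mean and population standard deviation
#' (divisor n) across members, mirroring the mean +/- sd bands of
#' ensemble simulation.
#'
#' @param ensemble an [Ensemble-class].
#' @param expression an [ExpressionTable-class] containing `cellLine`.
#' @param cellLine id of the line to predict.
#' @param conditions named list of [SimulationCondition-class]; defaults
#'   to the ensemble's training conditions.
#' @param mapping a [GeneMapping-class]; defaults to the fixture mapping
#'   of the trained model's expression species via the problem.
#' @return list of class `sigdyn_prediction`: per observable a list with
#'   `mean` and `sd` matrices (time x condition), plus `timeGrid`,
#'   `conditionNames`, `nMembers`, `cellLine`.
#' @export
predictCellLine <- function(ensemble, expression, cellLine,
                            conditions = NULL, mapping = NULL) {
  stopifnot(is(ensemble, "Ensemble"))
  if (!length(ensemble@members)) stop("empty ensemble", call. = FALSE)
  problem <- ensemble@problem
  model <- problem@model
  conditions <- conditions %||% problem@conditions
  mapping <- mapping %||% miniErbBMapping()
  if (!cellLine %in% cellLineIds(expression))
    stop("cell line not in expression table: ", cellLine, call. = FALSE)
  grid <- conditions[[1]]@timeGrid

  obsNames <- observableNames(model)
  condNames <- names(conditions)
  n <- length(ensemble@members)
  acc <- lapply(obsNames, function(ob)
    array(NA_real_, c(length(grid), length(condNames), n)))
  names(acc) <- obsNames

  for (k in seq_len(n)) {
    member <- ensemble@members[[k]]
    parts <- .splitCandidate(member$params, problem@space)
    kinetics <- problem@fixedKinetics
    kinetics[names(parts$kinetics)] <- parts$kinetics
    weights <- problem@fixedWeights
    weights[names(parts$weights)] <- parts$weights
    sim <- normalizeTraces(simulateLineRaw(model, kinetics, weights,
                                           expression, mapping, cellLine,
                                           conditions))
    for (ob in obsNames) acc[[ob]][, , k] <- sim@traces[[ob]]
  }

  out <- lapply(obsNames, function(ob) {
    mean <- apply(acc[[ob]], c(1, 2), mean)
    sd <- sqrt(apply(acc[[ob]], c(1, 2), function(v)
      mean((v - mean(v))^2)))
    dimnames(mean) <- dimnames(sd) <- list(NULL, condNames)
    list(mean = mean, sd = sd)
  })
  names(out) <- obsNames
  structure(list(observables = out, timeGrid = grid,
                 conditionNames = condNames, nMembers = n,
                 cellLine = cellLine),
            class = "sigdyn_prediction")
}

#' Write ensemble-prediction tables
#'
#' One TSV per observable (`prediction_<observable>.tsv`) with columns
#' time_min, condition, mean, sd.
#'
#' @param pred a `sigdyn_prediction` from [predictCellLine()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writePrediction <- function(pred, dir) {
  stopifnot(inherits(pred, "sigdyn_prediction"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  for (ob in names(pred$observables)) {
    p <- pred$observables[[ob]]
    df <- do.call(rbind, lapply(pred$conditionNames, function(cn)
      data.frame(time_min = pred$timeGrid, condition = cn,
                 mean = p$mean[, cn], sd = p$sd[, cn],
                 stringsAsFactors = FALSE)))
    writeTsv(df, file.path(dir, sprintf("prediction_%s.tsv", ob)))
  }
  invisible(dir)
}

#' Serialize an ensemble to a directory of text files
#'
#' One structured text file per member (`run_<seed>.tsv`: parameter name
#' and value, plus objective and seed rows) and an `index.tsv` with one
#' row per member. [readEnsemble()] restores the object given the
#' originating problem.
#'
#' @param ensemble an [Ensemble-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeEnsemble <- function(ensemble, dir) {
  stopifnot(is(ensemble, "Ensemble"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  idx <- data.frame(member = integer(), seed = numeric(),
                    objective = numeric(), file = character())
  for (k in seq_along(ensemble@members)) {
    m <- ensemble@members[[k]]
    fn <- sprintf("run_%d.tsv", as.integer(m$seed))
    df <- rbind(
      data.frame(key = names(m$params),
                 value = format(unname(m$params), digits = 17,
                                scientific = TRUE, trim = TRUE)),
      data.frame(key = ".objective",
                 value = format(m$objective, digits = 17,
                                scientific = TRUE, trim = TRUE)),
      data.frame(key = ".seed", value = format(m$seed, trim = TRUE)))
    ## atomic write: temp file then rename, so interrupted runs never
    ## leave half-written member files behind
    tmp <- file.path(dir, paste0(".tmp_", fn))
    writeTsv(df, tmp)
    file.rename(tmp, file.path(dir, fn))
    idx <- rbind(idx, data.frame(member = k, seed = m$seed,
                                 objective = m$objective, file = fn))
  }
  writeTsv(idx, file.path(dir, "index.tsv"))
  meta <- ensemble@metadata
  yaml::write_yaml(list(base_seed = meta$baseSeed, n_runs = meta$nRuns,
                        threshold = meta$threshold,
                        all_objectives = meta$allObjectives),
                   file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read an ensemble written by [writeEnsemble()]
#'
#' @param dir ensemble directory.
#' @param problem the [FitProblem-class] the ensemble was trained on.
#' @return an [Ensemble-class].
#' @export
readEnsemble <- function(dir, problem) {
  idx <- readTsv(file.path(dir, "index.tsv"))
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  members <- lapply(seq_len(nrow(idx)), function(k) {
    df <- readTsv(file.path(dir, idx$file[k]))
    vals <- setNames(as.numeric(df$value), df$key)
    list(params = vals[setdiff(names(vals), c(".objective", ".seed"))],
         objective = unname(vals[".objective"]),
         seed = unname(vals[".seed"]))
  })
  new("Ensemble", members = members,
      metadata = list(baseSeed = meta$base_seed, nRuns = meta$n_runs,
                      threshold = meta$threshold,
                      allObjectives = unlist(meta$all_objectives)),
      problem = problem)
}
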