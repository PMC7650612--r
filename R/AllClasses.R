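#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## Simulation-side classes
## ---------------------------------------------------------------------------

#' SimulationCondition: a stimulation protocol
#'
#' Describes one experimental condition: constant ligand doses applied at
#' time zero, the duration of the observation window, and the time grid (in
#' minutes) on which trajectories are reported.
#'
#' @slot ligandDoses named numeric, ligand name to dose in nM.
#' @slot duration numeric scalar, observation window in minutes.
#' @slot timeGrid numeric, sorted unique time points within `[0, duration]`.
#' @exportClass SimulationCondition
setClass("SimulationCondition",
  representation(ligandDoses = "numeric",
                 duration    = "numeric",
                 timeGrid    = "numeric"))

setValidity("SimulationCondition", function(object) {
  msg <- character()
  d <- object@ligandDoses
  if (length(d) && (is.null(names(d)) || any(!nzchar(names(d)))))
    msg <- c(msg, "ligandDoses must be a named numeric vector")
  if (any(!is.finite(d)) || any(d < 0))
    msg <- c(msg, "ligandDoses must be finite and non-negative")
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration <= 0)
    msg <- c(msg, "duration must be a single positive number")
  tg <- object@timeGrid
  if (!length(tg) || any(!is.finite(tg)))
    msg <- c(msg, "timeGrid must be non-empty and finite")
  else {
    if (is.unsorted(tg, strictly = TRUE))
      msg <- c(msg, "timeGrid must be strictly increasing (sorted, unique)")
    if (min(tg) < 0 || max(tg) > object@duration)
      msg <- c(msg, "timeGrid must lie within [0, duration]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationCondition
#'
#' @param ligandDoses named numeric vector of ligand doses (nM), e.g.
#'   `c(EGF = 10, HRG = 0)`.
#' @param duration observation window in minutes (default 120).
#' @param timeGrid report times in minutes; defaults to every 5 min.
#' @return a [SimulationCondition-class] object.
#' @examples
#' simulationCondition(c(EGF = 10, HRG = 0))
#' @export
simulationCondition <- function(ligandDoses, duration = 120,
                                timeGrid = NULL) {
  if (length(duration) != 1L || !is.finite(duration) || duration <= 0)
    stop("duration must be a single positive number", call. = FALSE)
  if (is.null(timeGrid)) timeGrid <- seq(0, duration, by = 5)
  new("SimulationCondition", ligandDoses = ligandDoses,
      duration = as.numeric(duration), timeGrid = as.numeric(timeGrid))
}

#' ReactionModel: an ODE signaling model
#'
#' The model abstraction around which the package is organised: an ordered
#' species list, an ordered parameter list, a deterministic right-hand side,
#' a builder translating expression-derived amounts into a full initial
#' state (and, for models whose conserved totals are carried as parameters,
#' into updated parameters), and named observable readouts.
#'
#' @slot name model identifier.
#' @slot speciesNames ordered character vector of state variables.
#' @slot parameterNames ordered character vector of parameters (kinetic
#'   constants plus conserved totals; ligand doses are appended from the
#'   condition at simulation time).
#' @slot ligands character, names of ligand dose entries the rhs expects.
#' @slot rhsFun `function(t, state, params, doses)` returning the
#'   derivative vector; must be deterministic.
#' @slot native list with entries `func`, `initfunc`, `dllname` naming a
#'   compiled deSolve-convention implementation, or an empty list.
#' @slot initialBuilder `function(params, amounts)` returning
#'   `list(params=, state=)`; `amounts` is a named vector of
#'   expression-derived initial amounts.
#' @slot amountNames species amounts accepted by `initialBuilder`.
#' @slot expressionSpecies subset of `amountNames` that are
#'   expression-initialized (mapped to gene families).
#' @slot observables named list of `function(valuesMatrix)` readouts, each
#'   returning one value per time point.
#' @exportClass ReactionModel
setClass("ReactionModel",
  representation(name = "character",
                 speciesNames = "character",
                 parameterNames = "character",
                 ligands = "character",
                 rhsFun = "function",
                 native = "list",
                 initialBuilder = "function",
                 amountNames = "character",
                 expressionSpecies = "character",
                 observables = "list"))

setValidity("ReactionModel", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (anyDuplicated(object@speciesNames))
    msg <- c(msg, "duplicate species names")
  if (anyDuplicated(object@parameterNames))
    msg <- c(msg, "duplicate parameter names")
  if (!length(object@observables) || is.null(names(object@observables)) ||
      !all(vapply(object@observables, is.function, logical(1))))
    msg <- c(msg, "observables must be a named list of functions")
  if (!all(object@expressionSpecies %in% object@amountNames))
    msg <- c(msg, "expressionSpecies must be a subset of amountNames")
  if (length(msg)) msg else TRUE
})

#' Trajectory: one simulated time course
#'
#' @slot timeGrid minutes.
#' @slot values matrix time x species.
#' @slot success logical; `FALSE` signals integrator failure (the values
#'   are then not to be trusted and downstream objectives treat the
#'   candidate as infeasible).
#' @exportClass Trajectory
setClass("Trajectory",
  representation(timeGrid = "numeric", values = "matrix",
                 success = "logical"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@success) != 1L)
    msg <- c(msg, "success must be a single logical")
  if (isTRUE(object@success)) {
    if (nrow(object@values) != length(object@timeGrid))
      msg <- c(msg, "row count must equal time grid length")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite when success is TRUE")
  }
  if (length(msg)) msg else TRUE
})

#' ObservableTraces: observable readouts across conditions
#'
#' One matrix (time x condition) per observable, plus a normalization flag.
#' Normalization follows the convention used for the experimental data:
#' per observable, all entries are divided by the maximum pooled over every
#' time point and every condition (within one cell line), so the maximum of
#' each normalized observable is exactly 1 unless it is identically zero.
#'
#' @slot traces named list of time x condition matrices.
#' @slot timeGrid minutes.
#' @slot conditionNames condition identifiers (column order).
#' @slot normalized logical flag guarding against double normalization.
#' @exportClass ObservableTraces
setClass("ObservableTraces",
  representation(traces = "list", timeGrid = "numeric",
                 conditionNames = "character", normalized = "logical"))

setValidity("ObservableTraces", function(object) {
  msg <- character()
  if (is.null(names(object@traces)))
    msg <- c(msg, "traces must be a named list")
  for (nm in names(object@traces)) {
    m <- object@traces[[nm]]
    if (!is.matrix(m) || nrow(m) != length(object@timeGrid) ||
        ncol(m) != length(object@conditionNames))
      msg <- c(msg, sprintf("trace '%s' has wrong shape", nm))
  }
  if (length(object@normalized) != 1L)
    msg <- c(msg, "normalized must be a single logical")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Expression-side classes
## ---------------------------------------------------------------------------

#' ExpressionTable: gene-by-cell-line TPM matrix
#'
#' A thin [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' with a single `tpm` assay, gene symbols as row names and cell-line
#' identifiers as column names. Validity enforces finite, non-negative TPM
#' and unique symbols.
#'
#' @exportClass ExpressionTable
setClass("ExpressionTable", contains = "SummarizedExperiment")

setValidity("ExpressionTable", function(object) {
  msg <- character()
  if (!"tpm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "must carry a 'tpm' assay")
  else {
    m <- SummarizedExperiment::assay(object, "tpm")
    if (any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, "TPM values must be finite and non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene symbols (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "cell-line ids (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionTable from a TPM matrix
#'
#' @param tpm numeric matrix, genes x cell lines, with dimnames.
#' @return an [ExpressionTable-class].
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("EGFR", "ERBB3"), c("A", "B")))
#' expressionTable(m)
#' @export
expressionTable <- function(tpm) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = as.matrix(tpm)))
  new("ExpressionTable", se)
}

#' GeneMapping: species to gene-family mapping
#'
#' For each expression-initialized model species, the list of gene symbols
#' (family members / isoforms) whose TPM values are summed to infer the
#' species' protein amount. A symbol may belong to at most one species.
#'
#' @slot mapping named list, species name -> character vector of symbols.
#' @exportClass GeneMapping
setClass("GeneMapping", representation(mapping = "list"))

setValidity("GeneMapping", function(object) {
  msg <- character()
  m <- object@mapping
  if (!length(m) || is.null(names(m)) || any(!nzchar(names(m))))
    msg <- c(msg, "mapping must be a non-empty named list")
  else {
    if (!all(vapply(m, is.character, logical(1))))
      msg <- c(msg, "mapping entries must be character vectors")
    syms <- unlist(m, use.names = FALSE)
    if (anyDuplicated(syms))
      msg <- c(msg, paste0("gene symbol(s) mapped to more than one species: ",
                           paste(unique(syms[duplicated(syms)]),
                                 collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' @param mapping named list, species -> character vector of gene symbols.
#' @rdname GeneMapping-class
#' @export
geneMapping <- function(mapping) new("GeneMapping", mapping = mapping)

## ---------------------------------------------------------------------------
## Estimation-side classes
## ---------------------------------------------------------------------------

#' SearchSpace: box constraints for parameter search
#'
#' Kinetic constants are searched within `[0.1, 10] x` their reference
#' values; weighting factors within `[0.1, 100]` (absolute). The genetic
#' algorithm works in log10 coordinates of these bounds.
#'
#' @slot name searched quantity names.
#' @slot reference reference values (weights use 1).
#' @slot lower,upper box bounds on the natural scale.
#' @slot isWeight logical, TRUE for weighting factors.
#' @exportClass SearchSpace
setClass("SearchSpace",
  representation(name = "character", reference = "numeric",
                 lower = "numeric", upper = "numeric",
                 isWeight = "logical"))

setValidity("SearchSpace", function(object) {
  n <- length(object@name)
  msg <- character()
  if (anyDuplicated(object@name)) msg <- c(msg, "duplicate names")
  if (length(object@reference) != n || length(object@lower) != n ||
      length(object@upper) != n || length(object@isWeight) != n)
    msg <- c(msg, "slot lengths differ")
  else {
    if (any(object@lower <= 0)) msg <- c(msg, "bounds must be positive")
    if (any(object@lower >= object@upper))
      msg <- c(msg, "lower bound must be strictly below upper bound")
    bad <- !object@isWeight &
      (object@reference < object@lower | object@reference > object@upper)
    if (any(bad))
      msg <- c(msg, "kinetic reference values must lie within their bounds")
  }
  if (length(msg)) msg else TRUE
})

#' GAConfig: genetic-algorithm settings
#'
#' @slot popSize individuals per generation (must be at least twice the
#'   search dimension).
#' @slot nGenerations number of generations.
#' @slot nElite elite individuals copied unchanged each generation.
#' @slot blxAlpha blend-crossover spread parameter.
#' @slot convergenceWindow stop early after this many generations without
#'   improvement (`Inf` disables early stopping).
#' @slot seed RNG seed for the run.
#' @exportClass GAConfig
setClass("GAConfig",
  representation(popSize = "numeric", nGenerations = "numeric",
                 nElite = "numeric", blxAlpha = "numeric",
                 convergenceWindow = "numeric", seed = "numeric"))

setValidity("GAConfig", function(object) {
  msg <- character()
  if (object@popSize < 4) msg <- c(msg, "popSize must be at least 4")
  if (object@nGenerations < 1) msg <- c(msg, "nGenerations must be >= 1")
  if (object@nElite < 0 || object@nElite >= object@popSize)
    msg <- c(msg, "nElite must be in [0, popSize)")
  if (object@blxAlpha < 0) msg <- c(msg, "blxAlpha must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a GAConfig
#'
#' @param popSize population size (default 64).
#' @param nGenerations generations (default 100).
#' @param nElite elite count (default 1).
#' @param blxAlpha blend-crossover spread (default 0.5).
#' @param convergenceWindow early-stop window (default `Inf`, disabled).
#' @param seed RNG seed (default 1).
#' @return a [GAConfig-class].
#' @export
gaConfig <- function(popSize = 64, nGenerations = 100, nElite = 1,
                     blxAlpha = 0.5, convergenceWindow = Inf, seed = 1) {
  new("GAConfig", popSize = popSize, nGenerations = nGenerations,
      nElite = nElite, blxAlpha = blxAlpha,
      convergenceWindow = convergenceWindow, seed = seed)
}

#' FitProblem: joint objective over cell lines, conditions and observables
#'
#' Bundles a model, the training cell lines (each with its summed-TPM
#' amounts and normalized measurements), the stimulation conditions and
#' the search space into the objective evaluated by the optimizer.
#'
#' @slot model a [ReactionModel-class].
#' @slot lines named list; per line: `tpm` (named summed-TPM per species)
#'   and `meas` (named list observable -> time x condition matrix,
#'   normalized, NA where unmeasured).
#' @slot conditions named list of [SimulationCondition-class].
#' @slot space a [SearchSpace-class].
#' @slot fixedKinetics full named kinetic parameter vector; searched
#'   entries are overridden by the candidate.
#' @slot fixedWeights named weighting factors for species not searched.
#' @slot timeGrid measurement time grid (minutes).
#' @exportClass FitProblem
setClass("FitProblem",
  representation(model = "ReactionModel", lines = "list",
                 conditions = "list", space = "SearchSpace",
                 fixedKinetics = "numeric", fixedWeights = "numeric",
                 timeGrid = "numeric"))

setValidity("FitProblem", function(object) {
  msg <- character()
  if (!length(object@lines) || is.null(names(object@lines)))
    msg <- c(msg, "lines must be a named list")
  if (!length(object@conditions) || is.null(names(object@conditions)))
    msg <- c(msg, "conditions must be a named list")
  for (ln in names(object@lines)) {
    l <- object@lines[[ln]]
    if (!is.list(l) || !all(c("tpm", "meas") %in% names(l))) {
      msg <- c(msg, sprintf("line '%s' must have tpm and meas entries", ln))
      next
    }
    for (ob in names(l$meas)) {
      m <- l$meas[[ob]]
      if (!is.matrix(m) || nrow(m) != length(object@timeGrid) ||
          ncol(m) != length(object@conditions))
        msg <- c(msg, sprintf(
          "line '%s' observable '%s': measurement matrix must be time x condition on the problem grid",
          ln, ob))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ensemble: accepted parameter sets from repeated optimization runs
#'
#' @slot members list; per member: `params` (named, natural scale),
#'   `objective`, `seed`.
#' @slot metadata list: `baseSeed`, `nRuns`, `threshold`, `allObjectives`.
#' @slot problem the [FitProblem-class] the ensemble was trained on.
#' @exportClass Ensemble
setClass("Ensemble",
  representation(members = "list", metadata = "list",
                 problem = "FitProblem"))

setValidity("Ensemble", function(object) {
  msg <- character()
  for (m in object@members) {
    if (!all(c("params", "objective", "seed") %in% names(m)))
      msg <- c(msg, "each member needs params, objective, seed")
    else if (!is.finite(m$objective))
      msg <- c(msg, "member objective values must be finite")
  }
  if (length(msg)) unique(msg) else TRUE
})

## ---------------------------------------------------------------------------
## Sensitivity-side classes
## ---------------------------------------------------------------------------

#' SensitivityConfig: settings for initial-value sensitivity analysis
#'
#' The response metric is the time integral of an observable over
#' `[0, T]`; coefficients are log-log: `C = (ln M(f*x) - ln M(x)) / ln f`
#' with the default fold change `f = 2` (doubling).
#'
#' @slot T integration window in minutes (default 120).
#' @slot f multiplicative perturbation factor (default 2; must be positive
#'   and different from 1).
#' @slot observables observables to analyze (default pAkt and pcFos).
#' @slot conditions condition names to analyze.
#' @exportClass SensitivityConfig
setClass("SensitivityConfig",
  representation(T = "numeric", f = "numeric",
                 observables = "character", conditions = "character"))

setValidity("SensitivityConfig", function(object) {
  msg <- character()
  if (object@T <= 0) msg <- c(msg, "T must be positive")
  if (object@f <= 0 || object@f == 1)
    msg <- c(msg, "f must be positive and different from 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SensitivityConfig
#'
#' @param T integration window, minutes.
#' @param f perturbation fold change.
#' @param observables observable names.
#' @param conditions condition names.
#' @return a [SensitivityConfig-class].
#' @export
sensitivityConfig <- function(T = 120, f = 2,
                              observables = c("pAkt", "pcFos"),
                              conditions = c("EGF", "HRG")) {
  new("SensitivityConfig", T = T, f = f, observables = observables,
      conditions = conditions)
}

#' SensitivityMatrix: member-resolved control coefficients
#'
#' Long-format coefficients indexed by (ensemble member, species,
#' observable, condition). Species whose initial amount is zero are absent
#' (skipped), not recorded as zero. Entries whose perturbed simulation
#' failed carry status `"failed"`; zero-baseline metrics carry
#' `"undefined"`; both leave the coefficient as `NA`. No averaging is
#' performed anywhere in this class or its exports.
#'
#' @slot data data.frame with columns member, species, observable,
#'   condition, coefficient, status.
#' @slot config the [SensitivityConfig-class] used.
#' @exportClass SensitivityMatrix
setClass("SensitivityMatrix",
  representation(data = "data.frame", config = "SensitivityConfig"))

setValidity("SensitivityMatrix", function(object) {
  need <- c("member", "species", "observable", "condition",
            "coefficient", "status")
  if (!all(need %in% names(object@data)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  ok <- object@data$status == "ok"
  if (any(!is.finite(object@data$coefficient[ok])))
    return("coefficients with status 'ok' must be finite")
  TRUE
})
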