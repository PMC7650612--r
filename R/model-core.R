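#' @include AllClasses.R
NULL

## Default integrator settings: stiff-capable BDF with tight tolerances.
## Exposed through function arguments; these constants are the package-wide
## defaults referenced by the config layer.
.RTOL_DEFAULT <- 1e-6
.ATOL_DEFAULT <- 1e-9
## cap BDF steps at the minute scale: bounds global error accumulation and
## dense-output interpolation error on coarse reporting grids
.HMAX_DEFAULT <- 1

#' Simulate one condition of a reaction model
#'
#' Integrates the model ODEs with a stiff-capable backward-differentiation
#' (BDF) method on the condition's time grid. Malformed inputs (NaN in
#' parameters, negative initial amounts, bad grid) raise a validation
#' error; numerical failure of the integrator is *data*, not an error — it
#' is reported through the trajectory's `success` flag so that fitting
#' objectives can penalize the candidate instead of crashing.
#'
#' @param model a [ReactionModel-class].
#' @param params named numeric parameter vector covering
#'   `parameterNames(model)`.
#' @param initials named (or ordered) non-negative initial state vector.
#' @param condition a [SimulationCondition-class].
#' @param rtol,atol integrator tolerances (defaults 1e-6 / 1e-9).
#' @param hmax maximum internal step size in minutes (default 1).
#' @param useNative use the compiled right-hand side when the model ships
#'   one (default TRUE); set FALSE to force the R implementation.
#' @return a [Trajectory-class].
#' @examples
#' mod <- miniErbBModel()
#' tr <- miniErbBTruth()
#' ib <- buildInitialValues(c(R1 = 100, R3 = 100, X = 200, MEK = 150,
#'                            ERK = 200, Akt = 250),
#'                          rep(1, 6), mod, tr$kinetics)
#' simulateCondition(mod, ib$params, ib$state,
#'                   simulationCondition(c(EGF = 10, HRG = 0)))
#' @export
simulateCondition <- function(model, params, initials, condition,
                              rtol = .RTOL_DEFAULT, atol = .ATOL_DEFAULT,
                              hmax = .HMAX_DEFAULT, useNative = TRUE) {
  stopifnot(is(model, "ReactionModel"), is(condition, "SimulationCondition"))
  validObject(condition)

  params <- .fullParams(model, params)
  if (any(!is.finite(params)))
    stop("parameter vector contains non-finite values: ",
         paste(names(params)[!is.finite(params)], collapse = ", "),
         call. = FALSE)

  ns <- length(model@speciesNames)
  if (length(initials) != ns)
    stop("initials must have length ", ns, call. = FALSE)
  initials <- as.numeric(initials)
  if (any(!is.finite(initials)) || any(initials < 0))
    stop("initial state must be finite and non-negative", call. = FALSE)
  names(initials) <- model@speciesNames

  doses <- vapply(model@ligands, function(l)
    unname(condition@ligandDoses[l] %||% 0), numeric(1))
  doses[is.na(doses)] <- 0

  grid <- condition@timeGrid
  times <- if (grid[1] > 0) c(0, grid) else grid

  out <- NULL
  ok <- TRUE
  res <- try({
    if (useNative && length(model@native)) {
      out <- suppressWarnings(deSolve::ode(
        y = initials, times = times, parms = c(params, doses),
        func = model@native$func, initfunc = model@native$initfunc,
        dllname = model@native$dllname, method = "bdf",
        rtol = rtol, atol = atol, hmax = hmax))
    } else {
      rhs <- model@rhsFun
      out <- suppressWarnings(deSolve::ode(
        y = initials, times = times,
        func = function(t, y, p) list(rhs(t, y, p, doses)),
        parms = params, method = "bdf", rtol = rtol, atol = atol,
        hmax = hmax))
    }
  }, silent = TRUE)

  if (inherits(res, "try-error") || is.null(out) ||
      nrow(out) < length(times) || any(!is.finite(out))) {
    ok <- FALSE
  } else {
    istate <- attr(out, "istate")
    if (!is.null(istate) && istate[1] < 0) ok <- FALSE
  }

  if (!ok)
    return(new("Trajectory", timeGrid = grid,
               values = matrix(NA_real_, 0, ns,
                               dimnames = list(NULL, model@speciesNames)),
               success = FALSE))

  vals <- out[match(grid, times), model@speciesNames, drop = FALSE]
  rownames(vals) <- NULL
  new("Trajectory", timeGrid = grid, values = vals, success = TRUE)
}

## Reorder/complete a user parameter vector against the model's canonical
## parameter order. Unnamed vectors of the right length are accepted as-is.
.fullParams <- function(model, params) {
  pn <- model@parameterNames
  if (is.null(names(params))) {
    if (length(params) != length(pn))
      stop("unnamed parameter vector must have length ", length(pn),
           call. = FALSE)
    return(setNames(as.numeric(params), pn))
  }
  missing <- setdiff(pn, names(params))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  setNames(as.numeric(params[pn]), pn)
}

#' Compute observable readouts across conditions
#'
#' Applies each of the model's observable readouts to one trajectory per
#' condition and assembles raw (unnormalized) time x condition matrices.
#'
#' @param model a [ReactionModel-class].
#' @param trajectories named list of [Trajectory-class], one per condition;
#'   all must share one time grid and have succeeded.
#' @return a raw [ObservableTraces-class].
#' @export
computeObservables <- function(model, trajectories) {
  stopifnot(is(model, "ReactionModel"), length(trajectories) >= 1)
  if (is.null(names(trajectories)) || any(!nzchar(names(trajectories))))
    stop("trajectories must be a named list (condition names)", call. = FALSE)
  if (!all(vapply(trajectories, function(t) isTRUE(t@success), logical(1))))
    stop("cannot compute observables from a failed trajectory", call. = FALSE)
  grid <- trajectories[[1]]@timeGrid
  for (tr in trajectories)
    if (!identical(tr@timeGrid, grid))
      stop("all trajectories must share one time grid", call. = FALSE)

  condNames <- names(trajectories)
  traces <- lapply(model@observables, function(f) {
    m <- vapply(trajectories, function(tr) as.numeric(f(tr@values)),
                numeric(length(grid)))
    m <- matrix(m, nrow = length(grid), ncol = length(condNames),
                dimnames = list(NULL, condNames))
    m
  })
  new("ObservableTraces", traces = traces, timeGrid = grid,
      conditionNames = condNames, normalized = FALSE)
}

#' Normalize observable traces to a pooled maximum of 1
#'
#' Follows the convention applied to the experimental time courses: per
#' observable, every entry is divided by the maximum over *all* time points
#' and *all* conditions (within one cell line), so ligand-to-ligand
#' amplitude ratios are preserved. Minima are taken as 0 (observables are
#' non-negative with near-zero baselines). Observables that are identically
#' zero are left at zero. Re-normalizing an already normalized object is an
#' error, not a silent no-op.
#'
#' @param traces a raw [ObservableTraces-class].
#' @return a normalized [ObservableTraces-class].
#' @export
normalizeTraces <- function(traces) {
  stopifnot(is(traces, "ObservableTraces"))
  if (traces@normalized)
    stop("traces are already normalized; refusing to normalize twice",
         call. = FALSE)
  norm <- lapply(traces@traces, function(m) {
    mx <- max(m)
    if (mx > 0) m / mx else m
  })
  new("ObservableTraces", traces = norm, timeGrid = traces@timeGrid,
      conditionNames = traces@conditionNames, normalized = TRUE)
}

#' Flatten observable traces to a long data.frame
#'
#' @param traces an [ObservableTraces-class].
#' @return data.frame with columns observable, condition, time_min, value.
#' @export
tracesToDataFrame <- function(traces) {
  stopifnot(is(traces, "ObservableTraces"))
  do.call(rbind, lapply(names(traces@traces), function(ob) {
    m <- traces@traces[[ob]]
    do.call(rbind, lapply(seq_along(traces@conditionNames), function(j) {
      data.frame(observable = ob,
                 condition = traces@conditionNames[j],
                 time_min = traces@timeGrid,
                 value = m[, j],
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Write a trajectory or observable traces as TSV
#'
#' Tab-separated with a mandatory header row: a `time` column followed by
#' one column per species (trajectories) or per observable/condition pair
#' (traces).
#'
#' @param x a [Trajectory-class] or [ObservableTraces-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTraceTable <- function(x, path) {
  if (is(x, "Trajectory")) {
    if (!x@success) stop("cannot export a failed trajectory", call. = FALSE)
    df <- data.frame(time = x@timeGrid, x@values, check.names = FALSE)
  } else if (is(x, "ObservableTraces")) {
    cols <- list(time = x@timeGrid)
    for (ob in names(x@traces))
      for (cn in x@conditionNames)
        cols[[paste(ob, cn, sep = "_")]] <- x@traces[[ob]][, cn]
    df <- as.data.frame(cols, check.names = FALSE)
  } else stop("unsupported object", call. = FALSE)
  writeTsv(df, path)
}
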