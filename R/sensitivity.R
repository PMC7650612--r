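#' @include AllClasses.R model-core.R estimation.R
NULL

#' Cumulative response: time integral of an observable
#'
#' Trapezoidal integral of one observable under one condition over
#' `[0, T]` minutes. If `T` falls between grid points the trace is
#' linearly interpolated at `T`; a `T` beyond the simulated range is an
#' error.
#'
#' @param traces an [ObservableTraces-class].
#' @param observable observable name.
#' @param condition condition name.
#' @param T upper integration limit in minutes (default 120).
#' @return scalar integral (observable units x minutes).
#' @export
cumulativeResponse <- function(traces, observable, condition, T = 120) {
  stopifnot(is(traces, "ObservableTraces"))
  if (T <= 0) stop("T must be positive", call. = FALSE)
  g <- traces@timeGrid
  if (T > max(g))
    stop(sprintf("T = %g min is beyond the simulated range (max %g)",
                 T, max(g)), call. = FALSE)
  m <- traceMatrix(traces, observable)
  if (!condition %in% traces@conditionNames)
    stop("unknown condition: ", condition, call. = FALSE)
  y <- m[, condition]
  keep <- g <= T
  x <- g[keep]; yy <- y[keep]
  if (max(x) < T) {
    yT <- approx(g, y, xout = T)$y
    x <- c(x, T); yy <- c(yy, yT)
  }
  sum(diff(x) * (head(yy, -1) + yy[-1]) / 2)
}

#' Initial-value sensitivity coefficients for one parameter set
#'
#' Quantifies how the cumulative response (time integral over `[0, T]`)
#' of each analyzed observable changes when the initial amount of one
#' species is scaled by the factor `f`, as a dimensionless log-log control
#' coefficient:
#' \deqn{C_i = \frac{\ln M(f x_i) - \ln M(x_i)}{\ln f}}
#' where only species `i`'s amount is perturbed. Species whose initial
#' amount is zero are skipped entirely (no row is emitted). A perturbed
#' simulation that fails yields status `"failed"`; a zero baseline metric
#' yields `"undefined"`; both leave the coefficient `NA`. Positive
#' coefficients mean the metric increases with the amount.
#'
#' Raw (unnormalized) observables are integrated: normalization rescales
#' by a perturbation-dependent maximum and would distort the coefficient.
#'
#' @param model a [ReactionModel-class].
#' @param params full named parameter vector (kinetics; totals are
#'   overwritten from `amounts`).
#' @param amounts named numeric, expression-derived initial amounts per
#'   species (the quantities being perturbed).
#' @param config a [SensitivityConfig-class].
#' @param conditions named list of [SimulationCondition-class] covering
#'   `config@conditions`; defaults to single-ligand 10 nM stimuli on a
#'   1-minute grid over `[0, T]`.
#' @param member integer tag recorded in the output (default 1).
#' @return a [SensitivityMatrix-class] slice for this parameter set.
#' @export
initialValueSensitivity <- function(model, params, amounts, config =
                                      sensitivityConfig(),
                                    conditions = NULL, member = 1L) {
  stopifnot(is(model, "ReactionModel"), is(config, "SensitivityConfig"))
  validObject(config)
  checkNamedNumeric(amounts, "amounts")
  if (is.null(conditions)) {
    grid <- seq(0, config@T, by = 1)
    conditions <- lapply(config@conditions, function(l) {
      doses <- setNames(rep(0, length(model@ligands)), model@ligands)
      doses[l] <- 10
      simulationCondition(doses, duration = config@T, timeGrid = grid)
    })
    names(conditions) <- config@conditions
  }
  obsNames <- intersect(config@observables, observableNames(model))
  if (!length(obsNames))
    stop("none of the configured observables exist in the model",
         call. = FALSE)

  metricsFor <- function(am) {
    ib <- model@initialBuilder(params, am)
    trajs <- lapply(conditions, function(cond)
      simulateCondition(model, ib$params, ib$state, cond))
    if (!all(vapply(trajs, function(t) t@success, logical(1))))
      return(NULL)
    traces <- computeObservables(model, trajs)
    out <- expand.grid(observable = obsNames,
                       condition = names(conditions),
                       stringsAsFactors = FALSE)
    out$M <- mapply(function(ob, cn)
      cumulativeResponse(traces, ob, cn, T = config@T),
      out$observable, out$condition)
    out
  }

  base <- metricsFor(amounts)
  if (is.null(base))
    stop("baseline simulation failed; cannot compute sensitivities",
         call. = FALSE)

  analyzed <- names(amounts)[amounts > 0]
  rows <- list()
  for (sp in analyzed) {
    am2 <- amounts
    am2[sp] <- am2[sp] * config@f
    pert <- metricsFor(am2)
    for (r in seq_len(nrow(base))) {
      M0 <- base$M[r]
      if (is.null(pert)) {
        coefficient <- NA_real_; status <- "failed"
      } else if (M0 <= 0) {
        coefficient <- NA_real_; status <- "undefined"
      } else {
        coefficient <- (log(pert$M[r]) - log(M0)) / log(config@f)
        status <- "ok"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        member = as.integer(member), species = sp,
        observable = base$observable[r], condition = base$condition[r],
        coefficient = coefficient, status = status,
        stringsAsFactors = FALSE)
    }
  }
  new("SensitivityMatrix",
      data = if (length(rows)) do.call(rbind, rows) else
        data.frame(member = integer(), species = character(),
                   observable = character(), condition = character(),
                   coefficient = numeric(), status = character()),
      config = config)
}

#' Member-resolved sensitivity analysis over an ensemble
#'
#' Runs [initialValueSensitivity()] for every ensemble member on one cell
#' line, with that member's weighting factors applied to the line's
#' summed TPM. Coefficients are reported per member; nothing is averaged.
#'
#' @param ensemble an [Ensemble-class].
#' @param expression an [ExpressionTable-class].
#' @param cellLine cell-line id to analyze.
#' @param config a [SensitivityConfig-class].
#' @param mapping a [GeneMapping-class] (default: fixture mapping).
#' @return a [SensitivityMatrix-class].
#' @export
ensembleSensitivity <- function(ensemble, expression, cellLine,
                                config = sensitivityConfig(),
                                mapping = NULL) {
  stopifnot(is(ensemble, "Ensemble"))
  if (!length(ensemble@members)) stop("empty ensemble", call. = FALSE)
  problem <- ensemble@problem
  model <- problem@model
  mapping <- mapping %||% miniErbBMapping()
  tpm <- extractGenes(expression, mapping, cellLine)

  slices <- lapply(seq_along(ensemble@members), function(k) {
    member <- ensemble@members[[k]]
    parts <- .splitCandidate(member$params, problem@space)
    kinetics <- problem@fixedKinetics
    kinetics[names(parts$kinetics)] <- parts$kinetics
    weights <- problem@fixedWeights
    weights[names(parts$weights)] <- parts$weights
    amounts <- weights[names(tpm)] * tpm
    initialValueSensitivity(model, .padTotals(model, kinetics), amounts,
                            config = config, member = k)
  })
  new("SensitivityMatrix",
      data = do.call(rbind, lapply(slices, function(s) s@data)),
      config = config)
}

#' Export a sensitivity matrix as TSV tables
#'
#' Writes a long-format table (`sensitivity_long.tsv` with columns
#' member, species, observable, condition, coefficient, status; failed or
#' undefined entries leave the coefficient field empty) and one
#' heatmap-ready matrix per observable/condition pair
#' (`sensitivity_matrix_<observable>_<condition>.tsv`, members as rows,
#' species as columns). Outputs are member-resolved throughout.
#'
#' @param matrix a [SensitivityMatrix-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
exportSensitivity <- function(matrix, dir) {
  stopifnot(is(matrix, "SensitivityMatrix"))
  d <- matrix@data
  if (!nrow(d)) stop("empty sensitivity matrix", call. = FALSE)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  long <- d
  long$coefficient <- ifelse(long$status == "ok",
                             format(long$coefficient, digits = 17,
                                    scientific = TRUE, trim = TRUE), "")
  writeTsv(long, file.path(dir, "sensitivity_long.tsv"))

  for (ob in unique(d$observable)) for (cn in unique(d$condition)) {
    sub <- d[d$observable == ob & d$condition == cn, , drop = FALSE]
    if (!nrow(sub)) next
    members <- sort(unique(sub$member))
    species <- unique(sub$species)
    m <- base::matrix(NA_real_, length(members), length(species),
                      dimnames = list(members, species))
    for (r in seq_len(nrow(sub)))
      m[as.character(sub$member[r]), sub$species[r]] <-
        sub$coefficient[r]
    df <- data.frame(member = members, m, check.names = FALSE)
    writeTsv(df, file.path(dir, sprintf("sensitivity_matrix_%s_%s.tsv",
                                        ob, cn)))
  }
  invisible(dir)
}

#' Read back a long-format sensitivity table
#'
#' Inverse of the long-format export of [exportSensitivity()]; together
#' they round-trip a [SensitivityMatrix-class] exactly.
#'
#' @param path path to `sensitivity_long.tsv`.
#' @param config the [SensitivityConfig-class] used (defaults to the
#'   package default).
#' @return a [SensitivityMatrix-class].
#' @export
readSensitivityLong <- function(path, config = sensitivityConfig()) {
  df <- readTsv(path)
  df$coefficient <- suppressWarnings(as.numeric(df$coefficient))
  df$member <- as.integer(df$member)
  new("SensitivityMatrix", data = df, config = config)
}

#' Plot a sensitivity heatmap (members x species)
#'
#' Diverging base-graphics heatmap around zero: blue for negative
#' coefficients (metric decreases when the amount increases), red for
#' positive.
#'
#' @param matrix a [SensitivityMatrix-class].
#' @param observable,condition which slice to draw.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted coefficient matrix.
#' @export
plotSensitivity <- function(matrix, observable, condition, ...) {
  d <- matrix@data
  sub <- d[d$observable == observable & d$condition == condition, ,
           drop = FALSE]
  if (!nrow(sub)) stop("no entries for that observable/condition",
                       call. = FALSE)
  members <- sort(unique(sub$member))
  species <- unique(sub$species)
  m <- base::matrix(NA_real_, length(members), length(species),
                    dimnames = list(members, species))
  for (r in seq_len(nrow(sub)))
    m[as.character(sub$member[r]), sub$species[r]] <- sub$coefficient[r]
  lim <- max(abs(m), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  graphics::image(seq_along(species), seq_along(members), t(m),
                  col = pal, zlim = c(-lim, lim), xaxt = "n", yaxt = "n",
                  xlab = "species", ylab = "parameter set",
                  main = sprintf("%s, %s", observable, condition), ...)
  graphics::axis(1, seq_along(species), species, las = 2)
  graphics::axis(2, seq_along(members), members, las = 1)
  invisible(m)
}
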