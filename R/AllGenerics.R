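#' @include AllClasses.R
NULL

#' Accessors for sigdyn classes
#'
#' Small accessor generics in the Bioconductor style; user code should use
#' these instead of reaching into slots.
#'
#' @param object a sigdyn S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))
#' @rdname accessors
#' @export
setMethod("speciesNames", "ReactionModel", function(object) object@speciesNames)

#' @rdname accessors
#' @export
setGeneric("parameterNames",
           function(object) standardGeneric("parameterNames"))
#' @rdname accessors
#' @export
setMethod("parameterNames", "ReactionModel",
          function(object) object@parameterNames)

#' @rdname accessors
#' @export
setGeneric("observableNames",
           function(object) standardGeneric("observableNames"))
#' @rdname accessors
#' @export
setMethod("observableNames", "ReactionModel",
          function(object) names(object@observables))
#' @rdname accessors
#' @export
setMethod("observableNames", "ObservableTraces",
          function(object) names(object@traces))

#' @rdname accessors
#' @export
setGeneric("timeGrid", function(object) standardGeneric("timeGrid"))
#' @rdname accessors
#' @export
setMethod("timeGrid", "Trajectory", function(object) object@timeGrid)
#' @rdname accessors
#' @export
setMethod("timeGrid", "ObservableTraces", function(object) object@timeGrid)
#' @rdname accessors
#' @export
setMethod("timeGrid", "SimulationCondition", function(object) object@timeGrid)

#' @rdname accessors
#' @export
setGeneric("trajectoryValues",
           function(object) standardGeneric("trajectoryValues"))
#' @rdname accessors
#' @export
setMethod("trajectoryValues", "Trajectory", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("succeeded", function(object) standardGeneric("succeeded"))
#' @rdname accessors
#' @export
setMethod("succeeded", "Trajectory", function(object) object@success)

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setMethod("isNormalized", "ObservableTraces",
          function(object) object@normalized)

#' Extract one observable's time x condition matrix
#' @param object an [ObservableTraces-class].
#' @param name observable name.
#' @return numeric matrix, time x condition.
#' @export
setGeneric("traceMatrix", function(object, name) standardGeneric("traceMatrix"))
#' @rdname traceMatrix
#' @export
setMethod("traceMatrix", "ObservableTraces", function(object, name) {
  if (!name %in% names(object@traces))
    stop("unknown observable: ", name, call. = FALSE)
  object@traces[[name]]
})

#' @rdname accessors
#' @export
setGeneric("tpmMatrix", function(object) standardGeneric("tpmMatrix"))
#' @rdname accessors
#' @export
setMethod("tpmMatrix", "ExpressionTable",
          function(object) SummarizedExperiment::assay(object, "tpm"))

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(object) standardGeneric("geneSymbols"))
#' @rdname accessors
#' @export
setMethod("geneSymbols", "ExpressionTable", function(object) rownames(object))

#' @rdname accessors
#' @export
setGeneric("cellLineIds", function(object) standardGeneric("cellLineIds"))
#' @rdname accessors
#' @export
setMethod("cellLineIds", "ExpressionTable", function(object) colnames(object))

#' @rdname accessors
#' @export
setGeneric("speciesGenes", function(object) standardGeneric("speciesGenes"))
#' @rdname accessors
#' @export
setMethod("speciesGenes", "GeneMapping", function(object) object@mapping)

#' @rdname accessors
#' @export
setGeneric("ensembleMembers",
           function(object) standardGeneric("ensembleMembers"))
#' @rdname accessors
#' @export
setMethod("ensembleMembers", "Ensemble", function(object) object@members)

#' @rdname accessors
#' @export
setGeneric("ensembleMetadata",
           function(object) standardGeneric("ensembleMetadata"))
#' @rdname accessors
#' @export
setMethod("ensembleMetadata", "Ensemble", function(object) object@metadata)

#' @rdname accessors
#' @export
setGeneric("sensitivityTable",
           function(object) standardGeneric("sensitivityTable"))
#' @rdname accessors
#' @export
setMethod("sensitivityTable", "SensitivityMatrix",
          function(object) object@data)

#' Search-space bounds as a data.frame
#' @param object a [SearchSpace-class].
#' @return data.frame with columns name, reference, lower, upper, isWeight.
#' @export
setGeneric("searchBounds", function(object) standardGeneric("searchBounds"))
#' @rdname searchBounds
#' @export
setMethod("searchBounds", "SearchSpace", function(object) {
  data.frame(name = object@name, reference = object@reference,
             lower = object@lower, upper = object@upper,
             isWeight = object@isWeight, stringsAsFactors = FALSE)
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ReactionModel", function(object) {
  cat("ReactionModel:", object@name, "\n",
      " ", length(object@speciesNames), "species;",
      length(object@parameterNames), "parameters;",
      length(object@observables), "observables (",
      paste(names(object@observables), collapse = ", "), ")\n",
      "  ligands:", paste(object@ligands, collapse = ", "),
      if (length(object@native)) " [compiled rhs available]" else "", "\n")
})

setMethod("show", "SimulationCondition", function(object) {
  cat("SimulationCondition:",
      paste(sprintf("%s=%g nM", names(object@ligandDoses),
                    object@ligandDoses), collapse = ", "),
      sprintf("| %g min, %d time points\n", object@duration,
              length(object@timeGrid)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points x %d species [%s]\n",
              length(object@timeGrid), ncol(object@values),
              if (object@success) "ok" else "FAILED"))
})

setMethod("show", "ObservableTraces", function(object) {
  cat(sprintf("ObservableTraces: %s | %d time points x %d conditions (%s)\n",
              paste(names(object@traces), collapse = ", "),
              length(object@timeGrid), length(object@conditionNames),
              if (object@normalized) "normalized" else "raw"))
})

setMethod("show", "GeneMapping", function(object) {
  cat("GeneMapping:", length(object@mapping), "species\n")
  for (sp in names(object@mapping))
    cat(sprintf("  %-8s <- %s\n", sp,
                paste(object@mapping[[sp]], collapse = " + ")))
})

setMethod("show", "SearchSpace", function(object) {
  cat(sprintf("SearchSpace: %d quantities (%d kinetic, %d weights), log10 search\n",
              length(object@name), sum(!object@isWeight),
              sum(object@isWeight)))
})

setMethod("show", "FitProblem", function(object) {
  cat(sprintf("FitProblem: model '%s', %d training lines (%s), %d conditions, %d searched quantities\n",
              object@model@name, length(object@lines),
              paste(names(object@lines), collapse = ", "),
              length(object@conditions), length(object@space@name)))
})

setMethod("show", "Ensemble", function(object) {
  objs <- vapply(object@members, `[[`, numeric(1), "objective")
  cat(sprintf("Ensemble: %d members | objective range [%.4g, %.4g] | threshold %.4g\n",
              length(object@members),
              if (length(objs)) min(objs) else NA,
              if (length(objs)) max(objs) else NA,
              object@metadata$threshold %||% NA))
})

setMethod("show", "SensitivityMatrix", function(object) {
  d <- object@data
  cat(sprintf("SensitivityMatrix: %d entries | %d members x %d species | observables: %s | f=%g, T=%g min\n",
              nrow(d), length(unique(d$member)), length(unique(d$species)),
              paste(unique(d$observable), collapse = ", "),
              object@config@f, object@config@T))
})
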