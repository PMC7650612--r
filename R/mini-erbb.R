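#' @include AllClasses.R model-core.R
NULL

.MINI_SPECIES <- c("R1a", "R3a", "Xa", "pMEK", "pERK", "pAkt",
                   "Fm", "Fos", "pFos", "Dusp")
.MINI_KINETICS <- c("ka1", "ki1", "ka3", "ki3", "kx", "kdx", "kfb",
                    "kmek", "kdmek", "kerk", "kderk", "kd", "kakt",
                    "kdakt", "ksm", "K", "n", "kdm", "ksf", "kdf",
                    "kpf", "kdpf", "ksd", "kdd")
.MINI_TOTALS <- c("R1tot", "R3tot", "Xtot", "MEKtot", "ERKtot", "Akttot")
## expression-initialized species and the total parameter each one feeds
.MINI_AMOUNT_TO_TOTAL <- c(R1 = "R1tot", R3 = "R3tot", X = "Xtot",
                           MEK = "MEKtot", ERK = "ERKtot", Akt = "Akttot")

#' Right-hand side of the reduced ErbB model (R implementation)
#'
#' A ten-state reduction of ErbB-family signaling: ligand-activated
#' receptors (ErbB1-like `R1a`, ErbB3-like `R3a`) drive a Ras-like node
#' `Xa`, the MEK/ERK cascade and the Akt branch; ERK induces c-Fos mRNA
#' (`Fm`) through a Hill function, c-Fos protein (`Fos`) is phosphorylated
#' by ERK to `pFos`, and an ERK-induced phosphatase (`Dusp`) closes a
#' negative feedback on ERK (with a second, faster feedback of ERK onto
#' the Ras-like node). Conserved totals (receptor, cascade and Akt
#' amounts) are parameters set from expression data, so every state starts
#' at zero in the resting condition.
#'
#' An equivalent compiled implementation is used by default for speed;
#' this R version defines the reference semantics and is cross-checked
#' against the compiled one in the test suite.
#'
#' @param t time (minutes; unused, the system is autonomous).
#' @param state named numeric state vector (10 species).
#' @param params named numeric vector (24 kinetic constants + 6 totals).
#' @param doses named numeric, `c(EGF=, HRG=)` in nM.
#' @return numeric derivative vector, same order as `state`.
#' @export
miniErbBRhs <- function(t, state, params, doses) {
  with(as.list(c(state, params)), {
    EGF <- unname(doses[["EGF"]])
    HRG <- unname(doses[["HRG"]])
    S <- R1a + R3a
    e <- max(pERK, 0)
    hill <- e^n / (K^n + e^n)
    c(ka1 * EGF * (R1tot - R1a) - ki1 * R1a,
      ka3 * HRG * (R3tot - R3a) - ki3 * R3a,
      kx * S * (Xtot - Xa) - kdx * (1 + kfb * pERK) * Xa,
      kmek * Xa * (MEKtot - pMEK) - kdmek * pMEK,
      kerk * pMEK * (ERKtot - pERK) - kderk * (1 + kd * Dusp) * pERK,
      kakt * S * (Akttot - pAkt) - kdakt * pAkt,
      ksm * hill - kdm * Fm,
      ksf * Fm - kdf * Fos - kpf * pERK * Fos + kdpf * pFos,
      kpf * pERK * Fos - kdpf * pFos - kdf * pFos,
      ksd * pERK - kdd * Dusp)
  })
}

#' The reduced ErbB -> ERK/Akt -> c-Fos model
#'
#' Builds the packaged ten-species [ReactionModel-class]: two
#' ligand-specific receptors, a Ras-like transducer, the MEK/ERK cascade,
#' the Akt branch, immediate-early c-Fos induction and a DUSP-mediated
#' negative feedback. Observables are `pAkt`, `pERK` and `pcFos` (the
#' phosphorylated c-Fos state).
#'
#' Expression-derived amounts map onto the conserved totals: species
#' `R1, R3, X, MEK, ERK, Akt` set the parameters `R1tot ... Akttot`;
#' optional amounts for `Fm`, `Fos`, `pFos`, `Dusp` set those states'
#' initial values directly (all default to 0; active/phosphorylated
#' species always start at 0).
#'
#' @return a [ReactionModel-class].
#' @examples
#' miniErbBModel()
#' @export
miniErbBModel <- function() {
  ib <- function(params, amounts) {
    checkNamedNumeric(amounts, "amounts")
    state <- setNames(numeric(length(.MINI_SPECIES)), .MINI_SPECIES)
    for (sp in names(amounts)) {
      if (sp %in% names(.MINI_AMOUNT_TO_TOTAL)) {
        params[[.MINI_AMOUNT_TO_TOTAL[[sp]]]] <- amounts[[sp]]
      } else if (sp %in% c("Fm", "Fos", "pFos", "Dusp")) {
        state[[sp]] <- amounts[[sp]]
      } else {
        stop("unknown amount entry: ", sp, call. = FALSE)
      }
    }
    list(params = params, state = state)
  }
  new("ReactionModel",
      name = "mini_erbb",
      speciesNames = .MINI_SPECIES,
      parameterNames = c(.MINI_KINETICS, .MINI_TOTALS),
      ligands = c("EGF", "HRG"),
      rhsFun = miniErbBRhs,
      native = list(func = "minierbb_derivs", initfunc = "minierbb_init",
                    dllname = "sigdyn"),
      initialBuilder = ib,
      amountNames = c(names(.MINI_AMOUNT_TO_TOTAL),
                      "Fm", "Fos", "pFos", "Dusp"),
      expressionSpecies = names(.MINI_AMOUNT_TO_TOTAL),
      observables = list(
        pAkt  = function(v) v[, "pAkt"],
        pERK  = function(v) v[, "pERK"],
        pcFos = function(v) v[, "pFos"]))
}

.miniTruthCache <- new.env(parent = emptyenv())

#' Ground-truth configuration of the reduced ErbB model
#'
#' Reads the versioned fixture configuration shipped with the package:
#' the true kinetic constants, the true per-species weighting factors, and
#' the gene families (isoform lists) whose summed TPM initializes each
#' conserved total. These values were chosen once so that every cascade
#' tier activates appreciably at 10 nM ligand and so that a cell line with
#' high ErbB3 / low ErbB1 expression shows the classic transient (EGF) vs
#' sustained (HRG) ERK phosphorylation contrast; they are fixture
#' configuration, not estimates.
#'
#' @return list with elements `kinetics` (named numeric, 24), `weights`
#'   (named numeric, 6), `geneFamilies` (named list of gene symbols).
#' @examples
#' str(miniErbBTruth())
#' @export
miniErbBTruth <- function() {
  if (!is.null(.miniTruthCache$truth)) return(.miniTruthCache$truth)
  path <- system.file("extdata", "mini_erbb_truth.yaml", package = "sigdyn",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  truth <- list(
    kinetics = unlist(raw$kinetics)[.MINI_KINETICS],
    weights = unlist(raw$weights),
    geneFamilies = lapply(raw$gene_families, unlist))
  stopifnot(!any(is.na(truth$kinetics)),
            identical(names(truth$weights),
                      names(.MINI_AMOUNT_TO_TOTAL)),
            identical(names(truth$geneFamilies),
                      names(.MINI_AMOUNT_TO_TOTAL)))
  .miniTruthCache$truth <- truth
  truth
}

#' Gene mapping of the reduced ErbB model
#'
#' @return a [GeneMapping-class] from the fixture's six
#'   expression-initialized species to their gene families.
#' @export
miniErbBMapping <- function() geneMapping(miniErbBTruth()$geneFamilies)
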