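## Shared fixtures, built in code at test time.

## A mid-range synthetic cell line as a named summed-TPM vector.
midTpm <- function() {
  c(R1 = 200, R3 = 200, X = 300, MEK = 300, ERK = 400, Akt = 600)
}

## Designated high-ErbB3/low-ErbB1 line used by the transient-vs-sustained
## regression test.
mcf7LikeTpm <- function() {
  c(R1 = 20, R3 = 400, X = 300, MEK = 300, ERK = 400, Akt = 600)
}

## Initial params/state for the fixture model from a TPM vector at truth.
truthInitials <- function(tpm = midTpm()) {
  mod <- miniErbBModel()
  truth <- miniErbBTruth()
  buildInitialValues(tpm, truth$weights, mod,
                     sigdyn:::.padTotals(mod, truth$kinetics))
}

egfCondition <- function(grid = seq(0, 120, by = 5)) {
  simulationCondition(c(EGF = 10, HRG = 0), duration = 120, timeGrid = grid)
}

hrgCondition <- function(grid = seq(0, 120, by = 5)) {
  simulationCondition(c(EGF = 0, HRG = 10), duration = 120, timeGrid = grid)
}

## Tiny plain-dialect expression file written to a tempfile.
writePlainExpr <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

## A small self-contained fit problem with a few free constants; noiseless
## data so the truth has objective ~ 0.
smallProblem <- function(free = c("ka1", "ki3", "kakt", "kdm"),
                         nLines = 4, seed = 11, noiseCv = 0,
                         freeWeights = FALSE) {
  s <- generateSyntheticCellLines(nLines = nLines, seed = seed,
                                  noiseCv = noiseCv)
  mod <- miniErbBModel()
  truth <- s$truth
  space <- searchSpace(truth$kinetics[free],
                       if (freeWeights) mod@expressionSpecies else character())
  prob <- fitProblem(mod, s$expression, s$mapping, s$measurements,
                     s$lineNames[seq_len(nLines - 1)], s$conditions, space,
                     truth$kinetics,
                     fixedWeights = truth$weights)
  list(synth = s, problem = prob, space = space, free = free)
}

## Truth candidate vector for a problem built by smallProblem().
truthCandidate <- function(sp) {
  truth <- miniErbBTruth()
  b <- searchBounds(sp)
  kin <- truth$kinetics[b$name[!b$isWeight]]
  wn <- b$name[b$isWeight]
  if (!length(wn)) return(kin)
  w <- truth$weights[sub("^w_", "", wn)]
  c(kin, setNames(w, wn))
}
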