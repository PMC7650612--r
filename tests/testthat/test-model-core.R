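test_that("zero stimulus with zero active initials is a fixed point", {
  mod <- miniErbBModel()
  truth <- miniErbBTruth()
  params <- sigdyn:::.padTotals(mod, truth$kinetics)
  params[c("R1tot", "R3tot", "Xtot", "MEKtot", "ERKtot", "Akttot")] <- 100
  state <- setNames(numeric(10), speciesNames(mod))

  ## rhs identically zero at the origin
  expect_equal(miniErbBRhs(0, state, params, c(EGF = 0, HRG = 0)),
               rep(0, 10))

  ## and the trajectory stays at zero
  cond <- simulationCondition(c(EGF = 0, HRG = 0), 120, seq(0, 120, 10))
  tj <- simulateCondition(mod, params, state, cond)
  expect_true(succeeded(tj))
  expect_equal(max(abs(trajectoryValues(tj))), 0)
})

test_that("malformed inputs raise validation errors, not failures", {
  mod <- miniErbBModel()
  ib <- truthInitials()
  cond <- egfCondition()

  bad <- ib$params
  bad["kerk"] <- NaN
  expect_error(simulateCondition(mod, bad, ib$state, cond), "non-finite")

  badState <- ib$state
  badState[1] <- -1
  expect_error(simulateCondition(mod, ib$params, badState, cond),
               "non-negative")

  expect_error(simulationCondition(c(EGF = 10), duration = -5), "duration")
  expect_error(simulationCondition(c(EGF = 10), duration = 120,
                                   timeGrid = c(0, 50, 50, 120)),
               "increasing")
})

test_that("default-tolerance integration matches tight-tolerance oracle", {
  ## oracle: the same ODE integrated at 10x tighter tolerances
  mod <- miniErbBModel()
  truth <- miniErbBTruth()
  cond <- egfCondition()
  condH <- hrgCondition()
  set.seed(401)
  worst <- 0
  for (i in 1:10) {
    k <- truth$kinetics * 10^runif(length(truth$kinetics), -1, 1)
    k["n"] <- truth$kinetics[["n"]]
    tpm <- 10^runif(6, 1, log10(500))
    names(tpm) <- names(miniErbBTruth()$weights)
    ib <- buildInitialValues(tpm, truth$weights, mod,
                             sigdyn:::.padTotals(mod, k))
    for (cc in list(cond, condH)) {
      a <- simulateCondition(mod, ib$params, ib$state, cc)
      b <- simulateCondition(mod, ib$params, ib$state, cc,
                             rtol = 1e-7, atol = 1e-10)
      if (!succeeded(a) || !succeeded(b)) next
      ## error relative to each species' trajectory scale (the scale on
      ## which trajectories enter the normalized objective)
      ref <- trajectoryValues(b)
      scale <- rep(pmax(apply(abs(ref), 2, max), 1e-12), each = nrow(ref))
      worst <- max(worst, max(abs(trajectoryValues(a) - ref) / scale))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("compiled and R right-hand sides integrate identically", {
  mod <- miniErbBModel()
  ib <- truthInitials()
  cond <- egfCondition()
  a <- simulateCondition(mod, ib$params, ib$state, cond, useNative = TRUE)
  b <- simulateCondition(mod, ib$params, ib$state, cond, useNative = FALSE)
  expect_true(succeeded(a) && succeeded(b))
  expect_equal(trajectoryValues(a), trajectoryValues(b), tolerance = 1e-10)
})

test_that("simulation is deterministic and respects conservation totals", {
  mod <- miniErbBModel()
  ib <- truthInitials()
  condH <- hrgCondition(seq(0, 120, 1))
  a <- simulateCondition(mod, ib$params, ib$state, condH)
  b <- simulateCondition(mod, ib$params, ib$state, condH)
  expect_identical(trajectoryValues(a), trajectoryValues(b))

  v <- trajectoryValues(a)
  tol <- 1e-6 * max(ib$params[c("R1tot", "R3tot", "Xtot", "MEKtot",
                                "ERKtot", "Akttot")])
  expect_true(all(v[, "R1a"] <= ib$params[["R1tot"]] + tol))
  expect_true(all(v[, "R3a"] <= ib$params[["R3tot"]] + tol))
  expect_true(all(v[, "Xa"] <= ib$params[["Xtot"]] + tol))
  expect_true(all(v[, "pMEK"] <= ib$params[["MEKtot"]] + tol))
  expect_true(all(v[, "pERK"] <= ib$params[["ERKtot"]] + tol))
  expect_true(all(v[, "pAkt"] <= ib$params[["Akttot"]] + tol))
  expect_true(all(v > -tol))
})

test_that("integrator failure is reported via the success flag", {
  ## a model whose rhs turns non-finite mid-run cannot be integrated
  bad <- new("ReactionModel", name = "bad", speciesNames = "x",
             parameterNames = "k", ligands = character(0),
             rhsFun = function(t, s, p, d) if (t > 1) NaN else 1,
             native = list(),
             initialBuilder = function(p, a) list(params = p,
                                                  state = c(x = 0)),
             amountNames = "x", expressionSpecies = "x",
             observables = list(obs = function(v) v[, "x"]))
  cond <- simulationCondition(c(L = 0), duration = 10,
                              timeGrid = seq(0, 10, 1))
  tj <- simulateCondition(bad, c(k = 1), c(x = 0), cond)
  expect_false(succeeded(tj))
})

test_that("computeObservables enforces its preconditions and shapes", {
  mod <- miniErbBModel()
  ib <- truthInitials()
  tE <- simulateCondition(mod, ib$params, ib$state, egfCondition())
  tH <- simulateCondition(mod, ib$params, ib$state, hrgCondition())

  tr <- computeObservables(mod, list(EGF = tE, HRG = tH))
  expect_identical(observableNames(tr), c("pAkt", "pERK", "pcFos"))
  ## column order matches condition order; identity readout equals the
  ## state column
  m <- traceMatrix(tr, "pERK")
  expect_identical(colnames(m), c("EGF", "HRG"))
  expect_equal(m[, "EGF"], unname(trajectoryValues(tE)[, "pERK"]))
  expect_false(isNormalized(tr))

  ## all-zero trajectory -> all observables zero
  zero <- new("Trajectory", timeGrid = timeGrid(tE),
              values = matrix(0, length(timeGrid(tE)), 10,
                              dimnames = list(NULL, speciesNames(mod))),
              success = TRUE)
  trz <- computeObservables(mod, list(EGF = zero))
  expect_equal(max(abs(traceMatrix(trz, "pAkt"))), 0)

  ## mismatched grids rejected
  tShort <- simulateCondition(mod, ib$params, ib$state,
                              egfCondition(seq(0, 120, 10)))
  expect_error(computeObservables(mod, list(EGF = tE, HRG = tShort)),
               "share one time grid")

  ## failed trajectory rejected
  fail <- new("Trajectory", timeGrid = numeric(0),
              values = matrix(numeric(0), 0, 10), success = FALSE)
  expect_error(computeObservables(mod, list(EGF = fail)), "failed")
})

test_that("normalization divides by the pooled max and refuses to repeat", {
  grid <- c(0, 1, 2)
  tr <- new("ObservableTraces",
            traces = list(a = matrix(c(2, 4, 8, 1, 0, 3), 3, 2,
                                     dimnames = list(NULL, c("EGF", "HRG"))),
                          z = matrix(0, 3, 2,
                                     dimnames = list(NULL, c("EGF", "HRG")))),
            timeGrid = grid, conditionNames = c("EGF", "HRG"),
            normalized = FALSE)
  nt <- normalizeTraces(tr)
  expect_true(isNormalized(nt))
  ## {2,4,8} with pooled max 8 -> {0.25, 0.5, 1}
  expect_equal(traceMatrix(nt, "a")[, "EGF"], c(0.25, 0.5, 1))
  ## pooled across conditions: second condition scaled by the same max
  expect_equal(traceMatrix(nt, "a")[, "HRG"], c(1, 0, 3) / 8)
  expect_equal(max(traceMatrix(nt, "a")), 1)
  ## all-zero observable stays zero, no division failure
  expect_equal(max(abs(traceMatrix(nt, "z"))), 0)
  ## no silent double normalization
  expect_error(normalizeTraces(nt), "already normalized")
})

test_that("trace export writes a header and one column per pair", {
  mod <- miniErbBModel()
  ib <- truthInitials()
  tE <- simulateCondition(mod, ib$params, ib$state, egfCondition())
  tr <- computeObservables(mod, list(EGF = tE))
  f <- tempfile(fileext = ".tsv")
  writeTraceTable(tr, f)
  df <- read.delim(f, check.names = FALSE)
  expect_identical(names(df),
                   c("time", "pAkt_EGF", "pERK_EGF", "pcFos_EGF"))
  expect_equal(df$pERK_EGF, unname(traceMatrix(tr, "pERK")[, "EGF"]))
})
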