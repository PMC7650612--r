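## Shared baseline for sensitivity tests: a mid-range line at fixture truth.
sensBaseline <- function() {
  mod <- miniErbBModel()
  truth <- miniErbBTruth()
  tpm <- c(R1 = 50, R3 = 300, X = 300, MEK = 250, ERK = 350, Akt = 500)
  list(model = mod, params = sigdyn:::.padTotals(mod, truth$kinetics),
       amounts = truth$weights * tpm)
}

test_that("cumulative response integrates traces on the requested window", {
  grid <- seq(0, 120, 1)
  mk <- function(y) new("ObservableTraces",
                        traces = list(a = matrix(y, length(grid), 1,
                                                 dimnames = list(NULL, "EGF"))),
                        timeGrid = grid, conditionNames = "EGF",
                        normalized = FALSE)
  ## constant 1 over 120 min -> 120; all-zero -> 0
  expect_equal(cumulativeResponse(mk(rep(1, 121)), "a", "EGF", 120), 120)
  expect_equal(cumulativeResponse(mk(rep(0, 121)), "a", "EGF", 120), 0)
  ## T beyond the simulated range is an error
  expect_error(cumulativeResponse(mk(rep(1, 121)), "a", "EGF", 200),
               "beyond the simulated range")
})

test_that("trapezoid on the 1-min grid matches a Simpson-rule oracle", {
  b <- sensBaseline()
  ib <- b$model@initialBuilder(b$params, b$amounts)
  grid <- seq(0, 120, 1)
  tj <- simulateCondition(b$model, ib$params, ib$state,
                          simulationCondition(c(EGF = 10, HRG = 0), 120,
                                              grid))
  tr <- computeObservables(b$model, list(EGF = tj))
  got <- cumulativeResponse(tr, "pERK", "EGF", 120)
  ## composite Simpson on the same 1-min refinement
  y <- traceMatrix(tr, "pERK")[, "EGF"]
  n <- length(y) - 1
  simpson <- sum((y[seq(1, n, 2)] + 4 * y[seq(2, n + 1, 2)] +
                    y[seq(3, n + 2, 2)]) / 3)
  expect_lt(abs(got - simpson) / simpson, 0.005)
})

test_that("species with no causal path to an observable score ~0", {
  b <- sensBaseline()
  ## give Dusp a nonzero initial amount; it decays and never touches pAkt
  sm <- initialValueSensitivity(b$model, b$params,
                                c(b$amounts, Dusp = 5),
                                sensitivityConfig(f = 2))
  d <- sensitivityTable(sm)
  dusp <- d[d$species == "Dusp" & d$observable == "pAkt", ]
  expect_equal(nrow(dusp), 2L)
  expect_true(all(abs(dusp$coefficient) < 1e-6))
})

test_that("coefficients match a small-step central-difference oracle", {
  b <- sensBaseline()
  sm <- initialValueSensitivity(b$model, b$params, b$amounts,
                                sensitivityConfig(f = 1.01))
  d <- sensitivityTable(sm)
  akt <- d[d$species == "Akt" & d$observable == "pAkt" &
             d$condition == "EGF", "coefficient"]
  expect_gt(akt, 0)

  metric <- function(am, sp, fac) {
    am[sp] <- am[sp] * fac
    ib <- b$model@initialBuilder(b$params, am)
    grid <- seq(0, 120, 1)
    tj <- simulateCondition(b$model, ib$params, ib$state,
                            simulationCondition(c(EGF = 10, HRG = 0), 120,
                                                grid))
    tr <- computeObservables(b$model, list(EGF = tj))
    cumulativeResponse(tr, "pAkt", "EGF", 120)
  }
  for (sp in c("Akt", "ERK", "X")) {
    got <- d[d$species == sp & d$observable == "pAkt" &
               d$condition == "EGF", "coefficient"]
    h <- 0.005
    oracle <- (log(metric(b$amounts, sp, 1 + h)) -
                 log(metric(b$amounts, sp, 1 - h))) /
      (log(1 + h) - log(1 - h))
    expect_lt(abs(got - oracle), 0.05, label = sp)
  }
})

test_that("a metric proportional to the amount has coefficient exactly 1", {
  ## 1-state model with zero dynamics and identity readout: the integral
  ## is x0 * T, so the log-log slope is 1 for any fold change f
  lin <- new("ReactionModel", name = "lin", speciesNames = "x",
             parameterNames = "k", ligands = character(0),
             rhsFun = function(t, s, p, d) 0, native = list(),
             initialBuilder = function(p, a)
               list(params = p, state = c(x = unname(a[["x"]]))),
             amountNames = "x", expressionSpecies = "x",
             observables = list(obs = function(v) v[, "x"]))
  conds <- list(base = simulationCondition(c(L = 0), 120, seq(0, 120, 1)))
  for (f in c(2, 1.5, 3)) {
    sm <- initialValueSensitivity(lin, c(k = 1), c(x = 3),
                                  sensitivityConfig(f = f,
                                                    observables = "obs",
                                                    conditions = "base"),
                                  conditions = conds)
    expect_equal(sensitivityTable(sm)$coefficient, 1, tolerance = 1e-10)
  }
})

test_that("exactly the nonzero-amount species are analyzed", {
  b <- sensBaseline()
  am <- b$amounts
  am["MEK"] <- 0
  sm <- initialValueSensitivity(b$model, b$params, am,
                                sensitivityConfig(f = 2))
  d <- sensitivityTable(sm)
  expect_setequal(unique(d$species), names(am)[am > 0])
  expect_false("MEK" %in% d$species)
  ## full grid: 5 nonzero species x 2 observables x 2 conditions
  expect_equal(nrow(d), 5L * 2L * 2L)
})

test_that("coefficient signs agree between f = 2 and f = 1.5 where |C| is material", {
  b <- sensBaseline()
  c2 <- sensitivityTable(initialValueSensitivity(
    b$model, b$params, b$amounts, sensitivityConfig(f = 2)))
  c15 <- sensitivityTable(initialValueSensitivity(
    b$model, b$params, b$amounts, sensitivityConfig(f = 1.5)))
  c101 <- sensitivityTable(initialValueSensitivity(
    b$model, b$params, b$amounts, sensitivityConfig(f = 1.01)))
  key <- function(d) paste(d$species, d$observable, d$condition)
  expect_identical(key(c2), key(c15))
  material <- abs(c101$coefficient) > 0.05
  expect_true(all(sign(c2$coefficient[material]) ==
                    sign(c15$coefficient[material])))
})

test_that("export writes member-resolved tables that round-trip", {
  b <- sensBaseline()
  s1 <- initialValueSensitivity(b$model, b$params, b$amounts,
                                sensitivityConfig(f = 2), member = 1L)
  s2 <- initialValueSensitivity(b$model, b$params, b$amounts * 1.3,
                                sensitivityConfig(f = 2), member = 2L)
  sm <- new("SensitivityMatrix", data = rbind(sensitivityTable(s1),
                                              sensitivityTable(s2)),
            config = s1@config)
  d <- file.path(tempdir(), "sensExp")
  exportSensitivity(sm, d)

  long <- read.delim(file.path(d, "sensitivity_long.tsv"))
  ## 2 members x 6 species x 2 observables x 2 conditions
  expect_equal(nrow(long), 2L * 6L * 2L * 2L)
  expect_true(file.exists(file.path(d, "sensitivity_matrix_pAkt_EGF.tsv")))
  mtx <- read.delim(file.path(d, "sensitivity_matrix_pcFos_HRG.tsv"),
                    check.names = FALSE)
  expect_equal(nrow(mtx), 2L)   # members as rows
  expect_equal(ncol(mtx), 1L + 6L)  # member column + species

  back <- readSensitivityLong(file.path(d, "sensitivity_long.tsv"),
                              sm@config)
  expect_equal(sensitivityTable(back)$coefficient,
               sensitivityTable(sm)$coefficient, tolerance = 1e-15)
  expect_identical(sensitivityTable(back)$species,
                   sensitivityTable(sm)$species)
  unlink(d, recursive = TRUE)
})

test_that("failed and undefined entries are marked, not zeroed", {
  ## model whose perturbed run fails: rhs explodes once x exceeds a gate
  gate <- new("ReactionModel", name = "gate", speciesNames = "x",
              parameterNames = "k", ligands = character(0),
              rhsFun = function(t, s, p, d)
                if (s[["x"]] > 5) NaN else 0.0,
              native = list(),
              initialBuilder = function(p, a)
                list(params = p, state = c(x = unname(a[["x"]]))),
              amountNames = "x", expressionSpecies = "x",
              observables = list(obs = function(v) v[, "x"]))
  conds <- list(base = simulationCondition(c(L = 0), 10, seq(0, 10, 1)))
  cfg <- sensitivityConfig(T = 10, f = 2, observables = "obs",
                           conditions = "base")
  sm <- initialValueSensitivity(gate, c(k = 1), c(x = 4), cfg,
                                conditions = conds)
  d <- sensitivityTable(sm)
  expect_identical(d$status, "failed")
  expect_true(is.na(d$coefficient))

  ## zero baseline metric -> undefined
  zero <- gate
  zero@rhsFun <- function(t, s, p, d) 0
  zero@observables <- list(obs = function(v) 0 * v[, "x"])
  smz <- initialValueSensitivity(zero, c(k = 1), c(x = 4), cfg,
                                 conditions = conds)
  expect_identical(sensitivityTable(smz)$status, "undefined")

  ## exported long table leaves the coefficient field empty
  outd <- file.path(tempdir(), "sensFail")
  exportSensitivity(sm, outd)
  lines <- readLines(file.path(outd, "sensitivity_long.tsv"))
  expect_match(lines[2], "\tfailed$")
  expect_match(lines[2], "\t\tfailed$")
  unlink(outd, recursive = TRUE)
})
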