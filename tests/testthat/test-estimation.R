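test_that("objective is zero at the generating truth on noiseless data", {
  sp <- smallProblem(noiseCv = 0, freeWeights = TRUE)
  cand <- truthCandidate(sp$problem@space)
  expect_lt(objectiveRSS(cand, sp$problem), 1e-8)
})

test_that("objective is the quadratic form of the residuals", {
  sp <- smallProblem(noiseCv = 0)
  prob <- sp$problem
  cand <- truthCandidate(prob@space)
  base <- objectiveRSS(cand, prob)
  ## perturb exactly one data point by +0.1 -> objective rises by 0.01
  prob2 <- prob
  l <- prob2@lines[[1]]
  l$meas$pERK[3, 1] <- l$meas$pERK[3, 1] + 0.1
  prob2@lines[[1]] <- l
  expect_equal(objectiveRSS(cand, prob2) - base, 0.01, tolerance = 1e-8)
})

test_that("objective decomposes over lines and ignores their order", {
  sp <- smallProblem(noiseCv = 0.1, seed = 21)
  prob <- sp$problem
  cand <- truthCandidate(prob@space)
  per <- objectiveRSS(cand, prob, perLine = TRUE)
  expect_equal(sum(per), objectiveRSS(cand, prob))

  probRev <- prob
  probRev@lines <- rev(prob@lines)
  expect_equal(objectiveRSS(cand, probRev), objectiveRSS(cand, prob))
})

test_that("integration failure maps to an infinite objective", {
  sp <- smallProblem(noiseCv = 0)
  prob <- sp$problem
  ## a model whose rhs breaks mid-run stands in for an untreatable
  ## stiffness failure; the objective must absorb it as +Inf
  badModel <- prob@model
  badModel@native <- list()
  badModel@rhsFun <- function(t, state, params, doses)
    if (t > 1) rep(NaN, 10) else rep(1, 10)
  prob@model <- badModel
  cand <- truthCandidate(prob@space)
  expect_identical(objectiveRSS(cand, prob), Inf)
})

test_that("GA minimizes a 5-D sphere and keeps a monotone history", {
  sp <- searchSpace(setNames(rep(1, 5), paste0("p", 1:5)))
  obj <- function(x) sum(log10(x)^2)  # global minimum 0 at the box center
  res <- gaOptimize(obj, sp, gaConfig(popSize = 50, nGenerations = 200,
                                      seed = 1))
  expect_lt(res$value, 1e-3)
  expect_false(is.unsorted(rev(res$history)))
  ## fixed seed -> identical result
  res2 <- gaOptimize(obj, sp, gaConfig(popSize = 50, nGenerations = 200,
                                       seed = 1))
  expect_identical(res$par, res2$par)
  expect_identical(res$history, res2$history)
})

test_that("GA solves a 1-D quadratic to within 1% of the minimizer", {
  sp <- searchSpace(c(a = 1))
  res <- gaOptimize(function(x) (x[["a"]] - 2)^2, sp,
                    gaConfig(popSize = 20, nGenerations = 60, seed = 3))
  expect_lt(abs(res$par[["a"]] - 2) / 2, 0.01)
})

test_that("GA validates its configuration and inputs", {
  sp <- searchSpace(setNames(rep(1, 5), paste0("p", 1:5)))
  expect_error(gaOptimize(function(x) 0, sp,
                          gaConfig(popSize = 8, nGenerations = 5)),
               "twice the search dimension")
  expect_error(gaOptimize(function(x) Inf, sp,
                          gaConfig(popSize = 10, nGenerations = 5)),
               "non-finite on every initial individual")
})

test_that("ensemble acceptance filters by threshold", {
  sp <- smallProblem(free = c("ka1", "kakt"), noiseCv = 0)
  cfg <- gaConfig(popSize = 8, nGenerations = 5, seed = 100)
  ens <- runEnsemble(sp$problem, cfg, nRuns = 3,
                     acceptanceThreshold = Inf)
  expect_s4_class(ens, "Ensemble")
  expect_length(ensembleMembers(ens), 3L)
  ## per-run seeds are base + run index
  expect_equal(vapply(ensembleMembers(ens), `[[`, numeric(1), "seed"),
               100 + 1:3)

  expect_error(runEnsemble(sp$problem, cfg, nRuns = 2,
                           acceptanceThreshold = -1),
               "empty ensemble.*best rejected")
})

test_that("prediction over identical members has zero spread", {
  sp <- smallProblem(free = c("ka1", "kakt"), noiseCv = 0)
  cfg <- gaConfig(popSize = 8, nGenerations = 4, seed = 7)
  ens <- runEnsemble(sp$problem, cfg, nRuns = 1, acceptanceThreshold = Inf)
  s <- sp$synth
  p1 <- predictCellLine(ens, s$expression, s$lineNames[4])
  expect_equal(max(abs(p1$observables$pERK$sd)), 0)

  ## duplicate the single member: mean unchanged, sd still zero
  ens3 <- ens
  ens3@members <- rep(ensembleMembers(ens), 3)
  p3 <- predictCellLine(ens3, s$expression, s$lineNames[4])
  expect_equal(p3$observables$pERK$mean, p1$observables$pERK$mean)
  expect_equal(max(abs(p3$observables$pAkt$sd)), 0)
  expect_error(predictCellLine(ens, s$expression, "NOPE"),
               "not in expression table")
})

test_that("prediction error does not grow as training noise shrinks", {
  ## scaled-down transfer check: same base seed, noise_cv 0.2 vs 0
  rmseAt <- function(cv) {
    s <- generateSyntheticCellLines(nLines = 4, seed = 31, noiseCv = cv)
    truth <- s$truth
    mod <- miniErbBModel()
    free <- c("ka1", "ki3", "kakt", "kdm")
    space <- searchSpace(truth$kinetics[free])
    prob <- fitProblem(mod, s$expression, s$mapping, s$measurements,
                       s$lineNames[1:3], s$conditions, space,
                       truth$kinetics, fixedWeights = truth$weights)
    ens <- runEnsemble(prob, gaConfig(popSize = 16, nGenerations = 30,
                                      seed = 50), nRuns = 2,
                       acceptanceThreshold = Inf)
    pred <- predictCellLine(ens, s$expression, s$lineNames[4])
    nl <- s$noiseless[[s$lineNames[4]]]
    errs <- unlist(lapply(names(pred$observables), function(ob)
      lapply(pred$conditionNames, function(cn) {
        sub <- nl[nl$observable == ob & nl$condition == cn, ]
        pred$observables[[ob]]$mean[match(sub$time_min, pred$timeGrid), cn] -
          sub$value
      })))
    sqrt(mean(errs^2))
  }
  expect_lte(rmseAt(0), rmseAt(0.2) + 1e-9)
})

test_that("ensembles round-trip through their text serialization", {
  sp <- smallProblem(free = c("ka1", "kakt"), noiseCv = 0)
  cfg <- gaConfig(popSize = 8, nGenerations = 4, seed = 11)
  ens <- runEnsemble(sp$problem, cfg, nRuns = 2, acceptanceThreshold = Inf)
  d <- file.path(tempdir(), "ensRT")
  writeEnsemble(ens, d)
  back <- readEnsemble(d, sp$problem)
  expect_equal(length(ensembleMembers(back)), length(ensembleMembers(ens)))
  for (k in seq_along(ensembleMembers(ens))) {
    expect_equal(ensembleMembers(back)[[k]]$params,
                 ensembleMembers(ens)[[k]]$params)
    expect_equal(ensembleMembers(back)[[k]]$objective,
                 ensembleMembers(ens)[[k]]$objective)
  }
  unlink(d, recursive = TRUE)
})

test_that("search bounds follow the 0.1-10x kinetic / 0.1-100 weight rule", {
  ref <- c(ka1 = 0.05, kerk = 0.008)
  sp <- searchSpace(ref, c("ERK", "Akt"))
  b <- searchBounds(sp)
  kin <- b[!b$isWeight, ]
  expect_equal(kin$lower, unname(ref) * 0.1)
  expect_equal(kin$upper, unname(ref) * 10)
  w <- b[b$isWeight, ]
  expect_equal(w$name, c("w_ERK", "w_Akt"))
  expect_equal(w$lower, c(0.1, 0.1))
  expect_equal(w$upper, c(100, 100))
})
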