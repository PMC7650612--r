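---
title: "Methods: predicting signaling dynamics from gene expression"
author: "sigdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting signaling dynamics from gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigdyn)
```

# The modeling idea

Growth-factor signaling networks produce strikingly different temporal
responses in different cell lines, even under identical stimulation. The
working hypothesis behind this package is that these differences are
carried mostly by the *abundances* of the network components, not by the
chemistry of their interactions: rate constants depend on the molecular
species involved and can be shared across cell lines, while each line's
initial protein amounts are inferred from its RNA-seq expression profile.
Under that assumption, a model trained jointly on several cell lines can
be transferred to an untrained line using nothing but that line's
expression data.

The workflow has four stages, each a module of this package:

1. **Simulation** (`simulateCondition()`, `computeObservables()`,
   `normalizeTraces()`): a `ReactionModel` couples an ODE right-hand side
   with observable readouts; trajectories are integrated with a
   stiff-capable BDF method.
2. **Expression-derived initial values** (`readExpressionTable()`,
   `extractGenes()`, `buildInitialValues()`): per model species, the TPM
   values of a small gene family (isoforms) are summed and scaled by a
   trainable, dimensionless *weighting factor* shared across cell lines.
3. **Joint estimation** (`objectiveRSS()`, `gaOptimize()`,
   `runEnsemble()`, `predictCellLine()`): a real-coded genetic algorithm
   minimizes the residual sum of squares over all training lines,
   conditions, observables and time points; repeated runs build a
   parameter ensemble whose mean ± sd simulation is the prediction.
4. **Sensitivity analysis** (`initialValueSensitivity()`,
   `ensembleSensitivity()`): log-log control coefficients of cumulative
   responses with respect to each nonzero initial amount, reported per
   ensemble member.

# The reduced ErbB fixture model

The packaged ten-species model keeps the structural features of
ErbB-family signaling at a size where every design choice is inspectable:

* two receptors with ligand-specific kinetics — an EGF-driven `R1`
  (ErbB1-like) and an HRG-driven `R3` (ErbB3-like);
* a Ras-like transducer `X` feeding the MEK/ERK cascade;
* an Akt branch driven directly by the active receptors;
* immediate-early gene induction: ERK activates c-Fos mRNA transcription
  through a Hill function, the protein is translated and phosphorylated
  by ERK;
* negative feedback: an ERK-induced DUSP-like phosphatase deactivates
  ERK, plus a fast ERK feedback on the Ras node.

Each cascade tier conserves its total (`R1tot`, ..., `Akttot`); the
totals are parameters set from expression data, and every
active/phosphorylated state starts at zero (resting, serum-starved
cells). Observables are `pAkt`, `pERK` and `pcFos`.

## Calibration of the fixture truth

The shipped ground-truth constants (`miniErbBTruth()`,
`inst/extdata/mini_erbb_truth.yaml`) were chosen once, before any
estimation experiments, under two qualitative constraints:

* every tier activates appreciably at the standard 10 nM ligand dose
  across the TPM range the generator draws from;
* a line with high ErbB3 and low ErbB1 expression reproduces the classic
  ligand dichotomy — *transient* ERK phosphorylation under EGF versus
  *sustained* ERK phosphorylation under HRG.

The mechanism implementing the dichotomy is deliberately simple: the
EGF receptor activates on a minutes timescale, so pERK peaks early and
the slower DUSP feedback (tens of minutes) then pushes it below half of
its peak by 120 min; the HRG receptor accumulates slowly, so pERK peaks
late and remains above half of its peak within the window. This is a
regression-tested property of the fixture configuration, not an
estimate.

Units are minutes, nM (ligands) and arbitrary TPM-scaled amount units.
Normalization makes the absolute amount scale irrelevant to the
objective.

# The synthetic-data generator

`generateSyntheticCellLines()` emulates the study design used for model
individualization: `nLines` cell lines share the fixture's true kinetics
and weighting factors and differ only in expression. Defaults are the
study conditions: four lines (three training, one held out), 10 nM
single-ligand stimuli, sampling at 0, 5, 15, 30, 45, 60, 90 and 120 min,
and multiplicative lognormal noise (unit mean) applied to the raw
observables before normalization. Per-gene TPM is drawn log-uniformly on
[10, 500], a realistic range for well-expressed signaling genes; the
gene families (e.g. `Akt` from AKT1+AKT2+AKT3) exercise the
isoform-summation rule with known truth.

The noise model is multiplicative because the quantified immunoblot data
the workflow targets have intensity-proportional errors and non-negative
signals; additive Gaussian noise would violate non-negativity at the many
near-zero samples. The default coefficient of variation (0.1) is typical
of replicate blot quantification; the estimation experiments below use
0.05 (averaged replicates) and 0 (identifiability analysis) where stated.

What the generator does *not* emulate: receptor-dimer combinatorics,
adaptor stoichiometry, basal (unstimulated) signaling, batch effects
between blots, and biological deviations from the shared-kinetics
assumption itself. Passing tests on synthetic data therefore demonstrate
correctness of the machinery and recoverability under the model's own
assumptions — not that real cell lines satisfy those assumptions.

# Normalization convention

Measurements and simulations are both scaled per observable and per cell
line by the maximum pooled over *all* time points and *both* ligand
conditions, so the EGF-to-HRG amplitude ratio is preserved — predictions
visibly depend on it. The minimum is taken as zero rather than the
observed minimum: observables are non-negative with near-zero baselines,
and subtracting a noisy baseline would amplify noise. Simulations are
normalized by their own maximum, independently of the data maximum, so a
candidate is compared to data in shape and relative amplitude.
All-zero observables are left at zero, and re-normalizing a normalized
object is an error rather than a silent no-op.

# Estimation

## Objective

`objectiveRSS()` is the plain (unweighted) residual sum of squares over
training lines, observables, conditions and measured time points, after
per-line normalization of the simulation. Measurement standard errors
are carried for plotting but do not weight the objective. Integration
failure of any candidate maps to `+Inf` — failure is data, and the
optimizer simply discards such candidates. The objective decomposes as a
sum of per-line terms and is invariant to line order (both are tested
properties).

## Genetic algorithm

The search runs in log10 coordinates of the box constraints — kinetic
constants within 0.1–10 times their reference values, weighting factors
within 0.1–100 — because these ranges span 2–3 decades and linear-scale
crossover would degenerate near the lower bound. Each generation draws
`popSize` children by blend (BLX-α, α = 0.5) crossover from uniformly
chosen parent pairs; parents and children then compete for survival
(μ+λ), which makes the best-so-far history non-increasing by
construction. As a diversity floor, survivors duplicating a
better-ranked individual are re-seeded uniformly from the prior — a
bookkeeping-free way of keeping the population spread. All knobs live in
`GAConfig`; a fixed seed fully determines a run.

## Ensemble

`runEnsemble()` launches independent GA runs with per-run seeds
`base + run index` and accepts runs whose final objective is at most the
acceptance threshold; by default the threshold is 1.5× the best
objective found, making "good-fitting" relative to the best run. The
default of 30 runs matches the standard ensemble size of the workflow;
the packaged estimation experiments use 6 scaled-down runs
(population 60, 70 generations) so that the full train-and-predict cycle
completes in a few minutes on one CPU — problem sizes chosen as the
package's own desk-scale defaults.

## Identifiability, and what prediction does and does not need

With all 23 searched kinetic constants and 6 weighting factors free, the
normalized training data leave many directions of parameter space flat:
amplitude-scaling combinations (for example a weighting factor against
its tier's catalytic constant) compensate each other almost exactly.
Ensemble members therefore scatter widely in parameter space while
fitting the data equally well — and held-out prediction still succeeds,
because prediction only requires the *map* from expression to normalized
dynamics, not the individual constants. This is the package's central
demonstration. When individual constants are of interest, the supported
approach is the clamped design used in the tests: fix all but a few
branch-separated constants (e.g. `ka1`, `ki3`, `kakt`, `kdm`), which are
then recovered within a few percent from noiseless data (population 32,
200 generations, averaged over 5 optimizer seeds in the packaged
checks).

# Sensitivity analysis

The response metric is the trapezoidal time integral of a raw observable
over [0, 120] min. Coefficients are log-log:

$$C_i = \frac{\ln M(f x_i) - \ln M(x_i)}{\ln f},$$

with doubling (`f = 2`) as the headline perturbation, making $C_i$ a
dimensionless control coefficient comparable across species and
magnitudes; `f` is configurable and the convention is declared in all
outputs. Raw rather than normalized observables are integrated because
the normalization maximum itself depends on the perturbation. Species
with zero initial amount are skipped entirely (no row, rather than a
fake zero); a zero baseline metric yields status `undefined`; a failed
perturbed simulation yields `failed`. Coefficients are computed per
ensemble member, with that member's weighting factors applied — outputs
are member-resolved and never averaged, so reproducible features can be
distinguished from parameter-set idiosyncrasies.

# Numerical choices

* **Integrator**: backward-differentiation (BDF) via deSolve, relative
  tolerance 1e-6, absolute tolerance 1e-9, maximum step 1 min. The step
  cap bounds global error accumulation and dense-output interpolation on
  coarse reporting grids; default-tolerance trajectories agree with
  10×-tighter integration to better than 1e-5 relative to each species'
  trajectory scale (tested).
* **Compiled right-hand side**: the fixture ships a C implementation
  (deSolve compiled-model convention) used by default during fitting; an
  R closure with identical semantics is kept on the model object and the
  two are cross-checked in the tests.
* **Hill coefficient**: `n` is a structural constant (default 2) and not
  searched; the 0.1–10× kinetic search rule would carry it outside its
  meaningful range [1, 4].
* **Degenerate inputs**: NaN parameters and negative initial states are
  validation errors; numerical failure is reported through the
  trajectory's `success` flag and absorbed as `+Inf` by the objective.
* **Determinism**: all randomness flows through per-call seeds; the
  caller's RNG state is saved and restored, and the end-to-end workflow
  writes byte-identical TSVs under a fixed base seed.

# Configuration and interfaces

Run configurations are YAML files mirroring `defaultRunConfig()`
(sectioned key/value; every default is printed into the
`resolved_config.yaml` copied to each output directory together with the
tool version). The command-line workflow —
`generate-data`, `simulate`, `fit`, `predict`, `sensitivity` — is a thin
Rscript (`inst/scripts/sigdyn.R`) over the exported `cli*()` functions.
Expression tables are read in a plain symbol-keyed dialect and in the
CCLE-RSEM-like dialect (Ensembl ids with version suffixes, a transcript
column, gzip-transparent); the packaged id-to-symbol table covers the
fixture families and the 19-species pathway mapping, and both mappings
are user-overridable via `readGeneMapping()`.

One deliberate deviation from a per-gene formulation: weighting factors
are defined per *species*, not per gene. Under the isoform-summation
rule, per-gene weights inside a sum are structurally unidentifiable
(only the weighted sum enters the model); a per-species factor preserves
the TPM-to-protein conversion role while keeping the search space
identifiable in principle.

# Known limitations

* The fixture is a structural reduction; it does not reproduce
  receptor internalization, dimer combinatorics or the full
  transcriptional circuit of large ErbB models.
* Initial states are zero-active; no serum-starvation steady state is
  pre-equilibrated.
* The full 29-dimensional search is intentionally over-parameterized for
  normalized data (see identifiability above); reported ensembles
  characterize predictive spread, not parameter posteriors.
* No gradient refinement, profile likelihoods or Bayesian sampling; no
  SBML import; deterministic ODEs only.
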