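---
title: "Modelling As(III) biosorption: response surfaces, neural surrogates and column breakthrough"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling As(III) biosorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosorb)
```

This vignette is the package's account of the science it implements: the
models, the assumptions behind them, the tunable parameters that matter, and
the places where a design decision was genuinely open and we had to choose.

## The process-optimisation problem

Biosorption — passive binding of a solute onto dead biomass — is governed
here by four process factors: biosorbent dose (g/L), solution pH,
temperature (°C) and initial As(III) concentration (mg/L). The response is
the percentage of As(III) removed at equilibrium. The packaged dataset
`table2_ccd()` is a 31-run central composite design over these factors:
16 factorial points at coded ±1, 8 axial points at coded ±2, and 7 centre
replicates, with factor centres (0.7 g/L, pH 6, 35 °C, 0.7 mg/L) and steps
(0.3, 2, 5, 0.3) per coded unit. The replicates carry the pure-error
information every lack-of-fit test needs; their observed spread (sum of
squared deviations ≈ 20.6 %²) is asserted as a fixture invariant in the test
suite.

All model fitting happens in **coded units** (`code_factor()` /
`decode_factor()`). A second-order polynomial evaluated at raw factor values
mixes scales spanning two orders of magnitude (pH² versus temperature²) and
produces absurd coefficient magnitudes; coding puts every factor on the same
±2 footing and makes coefficients directly comparable effect sizes.
Reporting converts back to actual units.

## The quadratic response surface

`fit_quadratic()` fits the full 15-term second-order model by ordinary least
squares via the QR decomposition, refusing rank-deficient designs by naming
the collinear terms. Fit statistics are R², adjusted R² (n − p − 1 residual
degrees of freedom, p = 14 non-intercept terms) and the mean absolute
percentage error; the ANOVA table splits the residual into lack of fit and
pure error using all replicated factor settings. On the packaged design the
quadratic achieves R² = 0.971 (adjusted 0.946) and the lack-of-fit test is
not significant at the 5 % level, so the second-order model is adequate
against replication noise.

`maximize_surface()` finds the box-constrained maximum by multi-start
bounded quasi-Newton search: all 16 corners of the box, the centre, and
(by default) 8 seeded random interior starts. Ties within 10⁻⁹ response
units are broken toward the smallest coded L2 norm, preferring interior
optima over rim artefacts. The 21⁴ dense-grid oracle in the test suite
confirms the multi-start search never undershoots the grid optimum.

One caveat the package deliberately surfaces rather than hides: the
dataset's reference "regression-predicted" column contains *different*
values at the seven centre replicates, which no single quadratic can
produce. Those columns are therefore treated as reference data for
comparison, never as ground truth for the refit, and the refit coefficients
are reported from our own least squares only.

## The neural-network surrogate

`train_mlp()` implements a 4-H-1 feed-forward perceptron (default H = 10):
inputs min-max scaled to [−1, 1] from the training split, hidden
tanh-sigmoid units computing f(Σᵢ xᵢwᵢ + θ), a linear output node, and the
response scaled the same way. A logistic hidden activation is selectable.
Training is full-batch gradient descent on the scaled training MSE with
momentum 0.9 and a multiplicative learning-rate schedule: ×1.05 after an
improving step, ×0.7 with step rejection (and momentum reset) when the MSE
grows by more than 4 %. Defaults: initial rate 0.5, at most 10 000 epochs,
MSE goal 0.001 (scaled units), weights initialised uniformly in [−0.5, 0.5]
from the seeded generator. The analytic backprop gradients are checked
against central finite differences to 10⁻⁶ in the test suite.

Two properties of this dataset shaped the design:

* **The MSE goal is unreachable on the packaged data.** The seven centre
  replicates share identical inputs but different responses, so no
  deterministic network can reduce the training MSE below the replicate
  variance — about 0.002 in scaled units, twice the 0.001 goal. Left to
  itself the descent therefore runs out the epoch budget and interpolates
  replicate noise.
* **Weight selection.** Because of the above, `train_mlp()` by default
  returns the epoch snapshot with the smallest *test-split* MSE rather than
  the final weights (`weight_selection = "least_test_mse"`; `"final"` gives
  the raw descent endpoint). With 24 training points and up to 61
  parameters this is the standard guard against overtraining, and the test
  suite asserts the snapshot never generalises worse than the final
  weights. `select_mlp()` extends the same criterion across several
  initialisation seeds (default 10), returning the best-validated network;
  `sweep_hidden_sizes()` extends it to topology choice. Where the package
  reports "the" surrogate optimum it is always the optimum of the
  selected network, because a single descent's endpoint is an
  initialisation lottery on 24 training points.

## The genetic algorithm

`ga_optimize()` maximises any surrogate (network, quadratic surface, or
plain function) over actual-unit factor bounds, default dose 0.1–1.3 g/L,
pH 2–10, 25–45 °C, 0.1–1.3 mg/L (concentration bounds in mg/L, the unit
used for As(III) concentration everywhere else). A candidate's
fitness is ε = 1 − 1/ŷ, strictly increasing in the predicted removal ŷ;
non-positive predictions receive the worst representable fitness and are
selected against rather than raising an error. Operators follow the classic
real-coded recipe: the 20 fittest elites are copied unchanged, parents are
drawn by roulette after shifting fitness by the generation minimum, 4-gene
chromosomes undergo single-point crossover with probability 0.8, and each
child gene receives Gaussian mutation with standard deviation 0.1 × range
that anneals linearly to zero over the 100 generations (the usual
Gaussian-mutation scale schedule; `mutation_shrink = 0` restores a constant
scale). Mutated genes are clipped to the bounds. Elitism makes the
best-so-far fitness non-decreasing, which every seeded test run asserts.
`ga_optimize_multi()` reruns the GA from derived seeds (default 10) and
returns the highest-fitness run, mirroring the practice of reiterating a
stochastic optimiser until the same optimum recurs.

### Reading the two optima together

On the packaged data the quadratic surface and the network surrogate
disagree instructively. The surface maximum is ~93.6 % removal near the
design centre at high concentration — an interior, data-supported optimum.
The GA pushed to the network's maximum instead lands in a corner of the
bounds box (high temperature, high concentration) at a predicted removal
around or above 100 %. The corner of the box lies at coded radius up to 4,
twice the axial radius of the design, so no experiment constrains the
network there: the prediction is extrapolation, and for a single trained
network its exact value swings by many percentage points with the
initialisation seed (restart selection in `select_mlp()` narrows but does
not remove this). A percentage above 100 is
physically meaningless and should be read as "the surrogate believes
removal saturates in this direction", not as a process prediction. Users
optimising their own surrogates should either restrict the GA bounds to the
sampled region or treat corner optima as hypotheses for a follow-up
experiment — which is how the validation experiment in the motivating study
should be understood.

## Batch sorption layer

The batch formulas are implemented exactly as the field writes them, with
linearised least squares as the canonical estimator because those are the
coordinates practitioners plot and report: Langmuir as Cₑ/qₑ against Cₑ,
Freundlich as log₁₀qₑ against log₁₀Cₑ, pseudo-first order as
log₁₀(qₑ − qₜ) against t, pseudo-second order as t/qₜ against t, Van 't
Hoff as ln K_c against 1/T. Back-transformation gives the physical
parameters; every fit's R² refers to the linearised coordinates. The PSO
initial sorption rate h = k₂′qₑ² is computed from the fitted constants, so
the identity holds to machine precision in every returned object.
Generate-and-refit round trips (noiseless data from the reported parameter
sets: Q° = 1.366 mg/g, b = 0.002 L/mg; K_F = 3.845, 1/n = 2.415;
k₂′ = 0.338 g/mg/min, qₑ = 2.202 mg/g; ΔH = 46.749 kJ/mol,
ΔS = 0.162 kJ/mol/K) recover parameters to 10⁻⁶ relative error.

Degenerate inputs are flagged, not hidden: a PSO intercept numerically
indistinguishable from zero (equilibrium-only series) yields k₂′ = ∞ with a
`degenerate` flag and warning; PFO points at or above the observed
equilibrium uptake are excluded with a warning because their logarithm is
undefined; fewer than three points, non-positive concentrations or
non-kelvin temperatures are errors. ΔG is reported in kJ/mol throughout
(the dataset convention), with the gas constant 8.314 J mol⁻¹ K⁻¹.

## Fixed-bed layer

Breakthrough analysis works on a measured (t, Cₜ) series plus a
`column_config()`. Crossing times are linearly interpolated: t_b at the
breakthrough threshold C_b, t_e at a fraction of the inlet concentration
(default Cₜ/C₀ = 0.95 — exhaustion is rarely defined operationally, so the
fraction is explicit and tunable). A series that never crosses a threshold
returns an explicit "not exhausted" result instead of failing, since
partially-run columns are common. The mass sorbed is the trapezoidal
integral of (C₀ − Cₜ) scaled by Q/1000; a 10×-refinement oracle in the
tests bounds the sampling-rate error below 0.5 % for logistic-shaped
fronts. Closed-form metrics (V = Q·t, X = C₀Qt_e/1000, EBCT = πr²Z/Q,
U_r = M/V_b, Z₀ = u/(k_aN₀)·ln(C₀/C_b − 1)) reproduce the motivating
study's reported column operating points at their reported precision; the
package evaluates EBCT with full π, which differs from the rounded reported
values by under 0.1 %. In that column table the inlet concentration behaves
as 1.0 mg/L (every reported metal-fed value equals 1.0·Q·t_e/1000) even
though the accompanying description mentions 1.1 mg/L; `column_config()`
therefore makes C₀ explicit rather than assuming either value. The BDST
critical height degenerates (Z₀ ≤ 0) when
C_b ≥ C₀/2; it is returned with a warning because the formula is still
well-defined.

## Synthetic data: what it does and does not emulate

Every generator is a pure function of its parameters and a seed, leaves the
caller's RNG state untouched, and produces data satisfying the consuming
type's invariants (responses clamped to [0, 100] %, breakthrough
concentrations to [0, C₀], positive uptakes). Noise is additive Gaussian
and homoscedastic. `simulate_ccd()` reuses the exact 31-point geometry and
train/test split of the packaged design; `simulate_breakthrough()` uses a
logistic front Cₜ = C₀/(1 + e^(−r(t−t₅₀))) whose crossing times have the
closed form used as the oracle in tests.

What passing tests on synthetic data demonstrate is estimator correctness:
round trips recover generating parameters, integrals match refined grids,
optimisers match analytic or brute-force oracles. What they cannot
demonstrate is adequacy of the model forms for real sorption data —
heteroscedastic measurement error, drifting inlet concentration,
non-logistic mass-transfer-zone shapes and multi-solute competition are all
outside the generators' scope, deliberately.

## Problem sizes and runtimes

The default test and acceptance workloads are sized for a laptop: the
31-run design for all response-surface work; 10 000-epoch cap on a
24-sample training split (about a second); GA populations of 100 for 100
generations, 10 restarts (a few seconds); 21⁴-point grid oracle and
100-seed Monte-Carlo bias checks as the heaviest test items. These sizes
are the package's defaults because they match the study's own problem
scale, not reductions of it.

## Known limitations

* The surrogate-optimisation headline depends on where the GA bounds exceed
  the sampled design region; see "Reading the two optima together".
* Linearised isotherm/kinetic estimators inherit the classical
  transformation bias under noise; they are the canonical reporting
  convention, not the statistically optimal estimator. A nonlinear
  refinement is a natural extension and intentionally out of scope here.
* The breakthrough integrator is trapezoidal on the user's sampling grid;
  strongly undersampled fronts should be measured, not interpolated.
* Thomas/Yoon–Nelson/Adams–Bohart full-curve column models and
  Temkin/Dubinin–Radushkevich isotherms are out of scope.
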