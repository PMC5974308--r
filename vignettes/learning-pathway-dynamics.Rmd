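---
title: "Learning metabolic pathway dynamics from multiomics time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning metabolic pathway dynamics from multiomics time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathdyn)
```

## The problem and the model

Engineered production pathways are usually modelled with kinetic rate laws:
for each metabolite, an ordinary differential equation whose right-hand side
is assembled by hand from Michaelis–Menten terms and literature constants.
`pathdyn` implements the data-driven alternative: given time-series
measurements of metabolite concentrations $m(t) \in \mathbb{R}^n$ and
pathway enzyme concentrations $p(t) \in \mathbb{R}^\ell$ for a handful of
strains, it learns the vector field

$$\dot m = f(m, p)$$

directly by regression, one regressor per metabolite, from
state–derivative training pairs. Trajectories for an unseen strain are then
predicted by integrating the learned field forward from the strain's first
observation, with that strain's measured protein series supplied as an
exogenous input. Nothing about the method is specific to a pathway, host or
product; the package ships a concrete instance — the limonene-producing
mevalonate pathway in *E. coli* — because it doubles as the ground truth
for validation.

The core modelling assumption is that the instantaneous metabolite and
protein concentrations determine the metabolite derivatives: there are no
unmeasured memory states. Protein dynamics are not modelled; the proteins
are an input trajectory, which matches how expression is manipulated
experimentally (promoters, RBSs) and keeps the learning problem
well-posed.

## The ground-truth simulator

`limonene_pathway_model()` builds a 10-state Michaelis–Menten system
(acetyl-CoA, acetoacetyl-CoA, HMG-CoA, mevalonate, mevalonate-5-P,
mevalonate-5-PP, IPP, DMAPP, GPP, limonene) driven by the nine pathway
enzymes AtoB, HMGS, HMGR, MK, PMK, PMD, Idi, GPPS and LS. Every reaction
is an irreversible single-substrate Michaelis–Menten flux
$v = k_\mathrm{cat} E S / (K_M + S)$ scaled linearly by its enzyme, with
three deliberate exceptions: AtoB consumes two acetyl-CoA per
condensation, Idi carries separate forward and reverse terms, and GPPS
multiplies saturation factors for its two substrates (IPP and DMAPP).
Acetyl-CoA is replenished by a constant source flux standing in for host
metabolism. States are clipped at zero inside the right-hand side so that
adaptive-step overshoot can never produce negative substrate
concentrations.

The kinetic constants shipped in
`inst/extdata/limonene_reference_params.yaml` are a synthetic reference
set, not a transcription of literature values. They were calibrated once,
before any validation experiments were designed, to two qualitative
requirements: the dynamics unfold over the full 72 h fermentation window
rather than in the first hour, and the intermediates (notably IPP/DMAPP
and GPP) rise, peak and decline — the behaviour that makes learning the
dynamics non-trivial. The reference enzyme-expression profiles stagger the
induction half-times so the downstream condensation and synthase steps
ramp later than the upper pathway, which is what produces the transient
intermediate accumulation.

Virtual strains share these kinetic constants and differ only in protein
expression. Each enzyme's profile is a leaky Hill curve
$p(t) = k_f\,t/(k_m + t) + k_l$; `generate_pool()` draws the three
coefficients per enzyme log-uniformly, spanning roughly two orders of
magnitude around the reference levels ($k_f \in [0.1, 10]$,
$k_m \in [2, 32]$ h, $k_l \in [0.005, 0.5]$). The log-uniform choice
reflects that expression perturbations act multiplicatively; the range
width is a package decision and directly controls how hard the
generalisation problem is — wider ranges put more held-out strains outside
any finite training set's coverage. By default strains are observed at 7
evenly spaced time points over 0–72 h, mimicking the experimental layout
of coupled proteomics/metabolomics fermentation studies.

What the generator deliberately does not emulate: measurement noise
(trajectories are exact up to integrator tolerance), missing values,
inter-replicate variability, and strain differences beyond expression
levels (e.g. enzyme variants with different $k_\mathrm{cat}$). Passing
tests on these conditions therefore demonstrate the machinery and its
scaling behaviour, not robustness to real measurement error.

## From sparse observations to training pairs

Real fermentation series have ~7 time points, far too few to train
per-metabolite regressors. The preprocessing pipeline
(`build_training_set()`) follows the smoothing–augmentation–
differentiation recipe:

1. **Savitzky–Golay smoothing** (`smooth_series()`), window 7 and
   polynomial order 2 by default. On a 7-point series the window equals
   the series and the filter degenerates to a single global quadratic fit,
   which is accepted behaviour.
2. **Augmentation** (`augment_series()`): cubic-spline interpolation over
   the filtered curve onto a uniform grid — 7 points become 200 by
   default. Interpolated values are clipped at zero where the spline
   overshoots; the grid never extends beyond the observed span.
3. **Differentiation** (`estimate_derivatives()`): central differences on
   the augmented grid, with first-order one-sided differences at the two
   boundary points so every time point yields a training example. On
   non-uniform grids the two-point formula $(m_{i+1}-m_{i-1})/(t_{i+1}-t_{i-1})$
   is used.

Each retained time point of each strain contributes one training row: the
concatenated $(m, p)$ concentrations as features (raw, unstandardised —
any scaling belongs to a candidate pipeline's own preprocessing) and the
estimated derivatives as targets.

One bias is worth knowing about: a 7-point window over a coarse grid spans
many hours and flattens fast transients, so derivative targets near a
sharp early peak are systematically biased on sparse grids. With ~100
observation points over 72 h the targets agree with the true right-hand
side essentially exactly; the package's oracle-recovery test uses such
dense noise-free series precisely to separate learner fidelity from
sampling distortion.

## Model selection

`fit_dynamics()` solves the supervised problem independently per
metabolite: every candidate pipeline in the search space is scored by
k-fold (default tenfold) cross-validated RMSE on that metabolite's
derivative target, the argmin wins (ties broken by fewer pipeline steps,
then fewer hyperparameters, then declaration order), and the winner is
refit on all rows. The engine is a deterministic exhaustive search over a
curated candidate registry — ordinary least squares, ridge (glmnet),
standardised k-nearest-neighbours (caret) and random forest (ranger) —
rather than an evolutionary pipeline search; the contract is the argmin of
cross-validated RMSE, not a particular search engine, and a deterministic
registry keeps repeated experiments reproducible and affordable.

**Fold policy.** Folds are grouped by strain whenever at least two strains
are present: all augmented rows of a strain fall on the same side of every
fold. Row-level shuffled folds look natural but are misleading here —
augmentation makes neighbouring rows of the same strain near-duplicates,
so row-level cross-validation rewards trajectory memorisation (nearest-
neighbour regressors win with near-zero CV error) while selecting models
that transfer poorly to unseen strains. Grouped folds measure exactly the
quantity the method is used for: predicting strains the model has never
seen. With a single training strain, plain shuffled row folds are the
fallback.

`assess_derivative_fit()` reports repeated shuffle-split train/test
Pearson $R^2$ per metabolite for the winning candidates — the
derivative-level accuracy diagnostic. Derivative accuracy does not bound
trajectory accuracy: integration compounds errors, which is why the
package's validation is closed-loop.

## Trajectory prediction

`predict_trajectory()` integrates the learned field with adaptive
Runge–Kutta 45 (Dormand–Prince, via deSolve), querying the strain's
protein concentrations at arbitrary interior times through a cubic-spline
interpolant clipped at zero (the same scheme as augmentation). Default
tolerances are `rtol = 1e-6`, `atol = 1e-9`; the repeated experiments pass
`rtol = 1e-3`, `atol = 1e-6` instead, which changes predicted final titers
by well under a percent on learned fields while cutting the number of
right-hand-side evaluations by an order of magnitude (piecewise-constant
forest fields force very small steps at tight tolerances). A refinement-
stability test asserts the tolerance insensitivity.

Two guard rails handle the fact that learned regressors are unconstrained:
the state passed to $f$ is clipped at zero (clip events are counted in the
diagnostics), and integration aborts with a divergence error when any
metabolite exceeds $10^6$ times its training-data maximum — a
deterministic failure in place of a runaway extrapolating field.

## Evaluation and experiments

`trajectory_rmse()` implements the continuous-time error
$\mathrm{RMSE} = \sqrt{\tfrac1n \sum_j \int_{t_0}^{t_f} (\bar m_j - m_j)^2\,dt}$
with both series spline-interpolated onto a common dense grid (601 points
by default) and integrated by the trapezoid rule; a constant offset $c$
recovers the closed form $c\sqrt{t_f - t_0}$. `percent_error()` divides
the time-averaged absolute error by the time-averaged absolute reference,
per metabolite — a prediction at twice the reference scores 100%;
zero-reference metabolites are flagged undefined and excluded from the
average. This normalisation is a package decision (the quantity has no
universal definition), so absolute percent-error values should only be
compared within it.

`ranking_experiment()` asks the practical question: can a model trained on
few strains order candidate designs by final product? For each
training-set size and repeat it fits the dynamics on sampled strains,
predicts final limonene for a set of held-out candidate strains by full
trajectory integration, and scores random triples — a success only when
the complete high/medium/low order is correct, so guessing succeeds at
1/6. Triples are drawn from a per-repeat candidate set
(`eval_strains`, default 12) so the number of integrations grows with the
candidate count rather than with $3\times$`triples`; a failed or divergent
integration scores its triples as failures. `scaling_experiment()`
measures trajectory RMSE on one fixed held-out strain as the training-set
size grows; both the mean error and its spread across repeats shrink with
more strains.

Default experiment sizes (pool of 300 strains, training sizes 2 and 10,
10 repeats, 20 triples per repeat, 50-point augmentation, the compact
search space) are the package's desk-scale choices: large enough for the
scaling signal to be unambiguous, small enough to run on a single CPU in
minutes. The same conditions back `scripts/acceptance.R`.

## The kinetic-fit baseline

`fit_kinetic_model()` is the classical comparator: all kinetic constants
free, fitted to observed trajectories by minimising the summed squared
residual over strains and time points. The optimizer is a hand-rolled
rand/1/bin differential evolution (no DE package is part of the package's
dependency footprint) over the bounded box, evolved in $\log_{10}$
parameter space — the default box spans $[10^{-12}, 10^9]$, twenty-one
decades, which is unsearchable in linear space. The mutation weight is
dithered per generation to slow premature population collapse, candidates
whose simulation diverges receive a large finite penalty, and the
population best is polished with Nelder–Mead followed by L-BFGS-B
(quasi-Newton line searches alone stall in the narrow curved valleys that
compensating constants create; the simplex handles these well and the
gradient step then sharpens). Bounds with `lower == upper` hold a constant
fixed, which is how the self-recovery test frees a 3-parameter subset
around the truth. Identifiability is explicitly not claimed: the fit
criterion is trajectory match, and the objective floor is set by protein
interpolation error, which is why self-recovery uses an hourly observation
grid. `compare_ml_vs_kinetic()` scores both predictors on the same
held-out strain with the same metrics.

## Proteomics insight

`pls_production_directions()` regresses final product titer on final-time
proteomics (columns standardised to unit variance — enzymes span scales)
with a two-block PLS (mixOmics) and returns scores, unit-norm loadings
and the protein ranking along component 1, the direction in proteomics
phase space that best covaries with production. Note that components
beyond the first live on deflated matrices, so only component 1 is a
direct projection of the centred data. `propose_and_simulate()` turns a
direction into candidate strains: final-time protein targets are displaced
additively (clipped at zero), each enzyme's Hill profile is rescaled
($k_f$ and $k_l$ jointly) to hit its displaced final value, and full
trajectories are predicted for every step size. Displacing final values
rather than whole profiles is a modelling choice — the insight analysis
lives in final-proteomics space, but the dynamics need complete input
trajectories.

## Known limitations

* Generalisation is bounded by coverage: held-out strains drawn near the
  edges of the two-decade expression ranges lie outside any small training
  set's hull, and tree-ensemble fields cannot extrapolate beyond their
  training range. Closed-loop trajectory errors for such strains are
  large even when in-distribution derivative accuracy is high.
* Error compounding is intrinsic: accurate derivatives do not guarantee
  accurate trajectories, and the package's acceptance checks are
  deliberately closed-loop for this reason.
* Percent errors depend on the chosen normalisation; RMSE values depend
  on concentration units. Learned models transfer only between datasets
  with consistent units.
* The simulator omits measurement noise; tests passing on it say nothing
  about noise robustness beyond what Savitzky–Golay smoothing provides.
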