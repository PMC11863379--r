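---
title: "Methods: model-based optimization of laboratory recipes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-based optimization of laboratory recipes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labopt)
```

`labopt` implements sequential model-based (Bayesian) optimization for
expensive physical experiments. This vignette is the package's account of
the underlying science: the model and its assumptions, the defaults and why
they were chosen, what the synthetic benchmark does and does not emulate,
and the numerical decisions that a maintainer or careful user should know
about. Minimization is assumed throughout: a score is something the
experimenter wants small (a color distance, an impurity level, a cost).

## Design spaces and encoding

A `search_space` is an ordered list of factors: real, integer, or
categorical. Internally every recipe is mapped to a unit cube: numeric
factors are rescaled linearly by `(x - low) / (high - low)` (bounds are
inclusive at both ends), and categorical factors become one-hot blocks. The
encoding makes the surrogate's length scales comparable across factors with
wildly different units (percent vs. microlitres), so their default search
range needs no per-problem tuning.

Decoding inverts the map; integer coordinates are rounded to the nearest
integer and one-hot blocks decode as the argmax. Two tie-break rules are
fixed and documented rather than left to chance: numeric rounding ties go
half away from zero (base R's `round` rounds half to even, which would make
77.5 snap down), and categorical argmax ties resolve to the lowest category
index. Spaces containing only categorical factors are rejected: with no
continuous direction the surrogate-plus-acquisition machinery degenerates,
and the package states this limitation as an error instead of guessing.

Many bench recipes can only be prepared at a fixed resolution (a pipetting
step, a balance readability). Numeric factors therefore carry an optional
`grid_step`, and `round_to_grid()` snaps a recipe to `low + k * step`
(ties half away from zero, clamped to bounds). Rounding is exposed as an
explicit helper and never applied silently inside the optimizer: the user
decides whether the suggestion or its rounded form is what was actually
run, and tells that. The benchmark harness rounds before scoring, because
its plate data only exist at the grid wells.

Constraints (mixture sums with a tolerance, value exclusions, value
restrictions) are enforced by rejection sampling when generating
candidates. No constrained-manifold parameterization is attempted; for the
low-dimensional spaces this package targets, rejection is simple, exact,
and fast. If fewer than 1 in 10,000 proposals are accepted over a million
draws, the region is reported as infeasible rather than looping forever.

## Initial design

The first `n_initial_points` (default 4) suggestions are a Latin hypercube:
each numeric factor's `[0, 1]` range is cut into `n` equal strata and
exactly one point is drawn uniformly *within* each stratum (via
`lhs::randomLHS`), with an independent stratum permutation per factor.
Drawing within strata rather than at stratum centres keeps the design
unbiased for the surrogate fit. Categorical factors receive a shuffled
balanced multiset of their categories. These points are computed at
optimizer creation from the seed, so the design depends only on
`(space, seed)` and is served before any model is fitted — the initial
experiments deliberately ignore all data.

## The Gaussian-process surrogate

Observations are modelled as draws from a Gaussian process with an
anisotropic Matérn-5/2 kernel plus independent Gaussian observation noise:

$$k(u, v) = \sigma_f^2\left(1 + \sqrt{5}\,r + \tfrac{5}{3}r^2\right)
e^{-\sqrt{5}\,r}, \qquad
r^2 = \sum_j \left(\frac{u_j - v_j}{\ell_j}\right)^2 .$$

Matérn-5/2 is the standard surrogate covariance for experiment
optimization: twice-differentiable sample paths, rough enough to track real
response surfaces, smooth enough for stable interpolation. It is the
package's default and a deliberate choice — no claim is made that any other
implementation uses the same kernel.

Targets are standardized to zero mean and unit variance before fitting, and
inputs live on the unit cube, so all hyperparameter bounds are scale-free:

| parameter | meaning | bounds | fallback |
|---|---|---|---|
| $\ell_j$ | length scale per encoded coordinate | $[10^{-3}, 10^{3}]$ | 0.3 |
| $\sigma_f^2$ | signal variance (standardized units) | $[10^{-6}, 10^{3}]$ | 1 |
| $\sigma_n^2$ | noise variance (standardized units) | $[10^{-10}, \mathrm{var}(y) + 1]$ | 0.01 |

Hyperparameters maximize the log marginal likelihood by bounded quasi-Newton
(`optim(method = "L-BFGS-B")` in log-parameter space) from the fixed
fallback start plus 5 log-uniform random restarts; the best of all starts is
kept, so the fit is never worse than the fallback. The noise floor
$10^{-10}$ doubles as jitter; if a Cholesky factorization still fails the
jitter escalates by decades. Degenerate inputs are handled explicitly: a
constant response (standard deviation below $10^{-12}$) skips scaling and
predicts the constant; a single observation fits and interpolates it.

Prediction returns two standard deviations: `std_model`, the epistemic
uncertainty of the surrogate, and `std_with_noise`, which adds
$\sigma_n^2$ — the difference between "how sure is the model about the mean
response" and "what spread should the next single measurement show".
Reports use the model-only band by default, with a flag to include noise.

## Acquisition functions

Three standard acquisitions are provided, all in the minimization
convention, selected by `acq_spec()`:

* **Expected improvement** (default), $\mathrm{EI} = (f^* - \mu - \xi)\Phi(z)
  + \sigma\phi(z)$ with $z = (f^* - \mu - \xi)/\sigma$, where $f^*$ is the
  best observed score. Default exploration margin $\xi = 0.01$, applied on
  the raw score scale (predictions are destandardized before the
  acquisition is evaluated). EI is the community default: parameter-light
  and empirically robust on desk-scale problems.
* **Probability of improvement**, $\Phi((f^* - \mu - \xi)/\sigma)$ — more
  exploitative.
* **Lower confidence bound**, $\mu - \kappa\sigma$ with $\kappa = 1.96$
  (a nominal 95% one-sided band); its minimizer is the suggestion.

All three reduce correctly in the $\sigma \to 0$ limit (EI becomes
$\max(f^* - \mu - \xi, 0)$, PI an indicator, LCB the mean).

The acquisition is maximized by scoring 1000 seeded uniform feasible
candidates, then polishing the 5 best by bounded quasi-Newton on the unit
cube. The GP acquisition surface is smooth, so a gradient-based polish with
numerical derivatives converges in a handful of iterations and respects the
box bounds natively. Integer and categorical factors are optimized through
their continuous relaxation; the polished point is decoded (snapped/argmax)
and re-scored before the final comparison, so the returned recipe is always
exactly representable. The candidate count balances desk-scale runtime
(about a second per suggestion) against argmax quality; tests verify the
suggestion beats 10,000 fresh random candidates on a 1-D toy.

## The ask/tell loop

`ask()` serves the initial design, then suggests by acquisition; `tell()`
records an observation. Three behaviours deserve explanation:

* **Idempotent asks.** An un-told suggestion is cached and returned
  unchanged by repeated asks. In a lab campaign an accidental second `ask`
  must not burn a second experiment.
* **Refit timing.** The surrogate is refitted lazily when a fit is actually
  needed (at a model-phase ask, or at tell once the initial design is
  complete), keyed on the observation count. Refitting eagerly on every
  tell would waste fits during batch imports of historical data.
* **Origins.** Observations are tagged `initial` while the initial design
  is being consumed, `model` when they match a model-phase suggestion, and
  `manual` otherwise — telling recipes that were never asked is explicitly
  allowed, to import pre-existing data.

Batch suggestions (`ask_batch`) use the constant-liar heuristic: after each
model-phase suggestion a pseudo-observation equal to the minimum
(`cl_min`, default — the most exploitative choice), mean, or maximum of the
real scores is imputed at it and the surrogate refitted, pushing later
suggestions away. The lies are discarded afterwards; the real observation
list is untouched.

Every stochastic step (initial design, surrogate restarts, candidate
generation) draws from a sub-seed derived deterministically from the
optimizer seed and the observation count. The whole loop is therefore a
pure function of `(space, settings, seed, told data)`: replaying the same
tells reproduces the identical suggestion sequence, which is what makes the
file-backed CLI sessions crash-safe — config plus append-only log *is* the
state, and everything else is reconstructed by replay.

`expected_min()` minimizes the predictive mean with the same
candidates-plus-polish scheme, additionally starting polish runs from every
observed recipe (the incumbent is always a candidate, so the reported
minimum can never be worse than the model's value at the best observation).
`partial_dependence()` averages the predictive mean over seeded background
samples of the remaining factors at each grid value of the chosen
factor(s) — the plot-ready summary of the fitted response surface.

## Multi-objective suggestion (NSGA-II)

For vector-valued scores the package runs NSGA-II over the space against an
evaluator — either per-objective surrogate means or a benchmark system.
Operator parameters follow the canonical published defaults: simulated
binary crossover with $\eta_c = 15$, $p_c = 0.9$; polynomial mutation with
$\eta_m = 20$, $p_m = 1/d$; binary tournament on (front rank, crowding
distance); elitist environmental selection from parents plus children.
Categorical blocks use uniform block crossover and resample-category
mutation, since SBX has no meaning on one-hot coordinates.

The crowding distance of an interior individual is the mean distance to its
two neighbours per objective, normalized by that objective's range, summed
over objectives (boundary individuals are infinite). This is half the
conventional neighbour-span form; the two differ by a constant factor, so
selection behaviour is identical.

One property worth stating because it surprises: the hypervolume covered by
the population is *not* exactly monotone across generations. When the first
front exceeds the population size, crowding-based truncation can shed tiny
slivers of hypervolume (fractions of a percent per step on the toy
bi-objective problem). That is a property of the canonical algorithm, not a
defect; the test suite checks near-monotone growth with a 0.1% relative
slack.

Constrained multi-objective optimization is not supported and raises an
error, as does a single-objective evaluator (use the ask/tell optimizer).

## The synthetic color plate

The benchmarking harness ships a synthetic stand-in for a measured 96-well
universal pH-indicator plate: acid 30–85% and indicator 5–40 µL, both in
steps of 5 (12 × 8 wells). Its construction:

* the acid fraction $a$ sets the pH through a sigmoid titration curve
  $\mathrm{pH} = p_{lo} + (p_{hi} - p_{lo}) / (1 + e^{s (a - a_{mid})})$
  with defaults $p_{lo} = 3$, $p_{hi} = 11$, $s = 10$ per unit acid
  fraction, $a_{mid} = 0.575$ (the centre of the acid range);
* the pH sets the hue by piecewise-linear interpolation in CIELAB between
  seven anchor colors (red at pH 3 through orange, yellow, green, teal and
  blue to violet at pH 11 — the qualitative sweep of a wide-range
  indicator);
* the indicator volume $v$ scales saturation: $a$ and $b$ are multiplied by
  $v/40$ and lightness fades to 100 (colorless) as $v \to 0$.

The target color is the generated color at acid 50%, indicator 30 µL — an
interior well — so the optimum lies exactly on the grid with ΔE = 0 by
construction, and a campaign's end-to-end success has an unambiguous
yardstick. Scores use the CIE76 ΔE (the CIELAB Euclidean distance);
CIEDE2000 would weight hue and chroma perceptually but adds nothing to a
benchmark whose zero is what matters. Recipes are grid-rounded before
lookup because the plate has no data between wells, and each recipe's
240 µL total volume (indicator solution topped up to 40 µL with water plus
200 µL acid/base mixture) is validated on every score.

What the generator does *not* emulate: a real buffer series' acid-to-pH
curve (the sigmoid is a labelled stand-in), measurement noise in the plate
colors themselves (noise is injected, controllably, by the `noise_spec`
instead: zero, constant-σ, or proportional-σ Gaussian), well-position
effects, and indicator chemistry beyond "more indicator, more saturated".
Passing benchmarks therefore demonstrate that the optimizer machinery finds
an on-grid optimum of a smooth-ish mixed response surface in few
experiments — not that any particular real plate would produce the same
trajectory or scores. Measured plate data with the same layout can be
swapped in via `grid_from_csv()` without code changes.

## Problem sizes and test design

The suite's simulations are sized for a desk machine: GP oracle checks use
5 training points against a dense `solve()` reimplementation (tolerance
1e-8); EI is checked against a $10^6$-draw Monte-Carlo estimate (tolerance
1e-3); non-dominated sorting is compared exactly with a brute-force
dominance oracle on 50 random 20-point, 3-objective instances; length-scale
recovery uses 40 points simulated from a known 1-D process; the end-to-end
campaign benchmark runs 24 experiments × 5 replicate seeds on the color
plate and checks the median true ΔE at the grid-rounded expected-minimum
recipe. Each replicate takes tens of seconds; the whole suite a few
minutes.

## Known limitations

* No conditional/hierarchical or log-scaled dimensions.
* All-categorical spaces unsupported (stated error).
* Constraints unsupported in multi-objective mode (stated error).
* The surrogate is a single GP; alternative surrogates (random forests,
  gradient boosting) are an extension point, not implemented.
* No entropy-search or knowledge-gradient acquisitions, and no portfolio
  mixing of acquisitions.
* Rejection sampling makes thin mixture-constraint regions expensive;
  tolerances below ~1% of a factor's range may hit the infeasibility guard.
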