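---
title: "Methods: quantifying reproductive Allee effects at a mapped spawning site"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying reproductive Allee effects at a mapped spawning site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralAllee)
```

## The scientific problem

Broadcast-spawning corals release eggs and sperm into the water column,
and successful fertilization requires that sperm from a neighbouring
colony reach the eggs before dilution makes encounter rates negligible.
For sessile animals this creates a *component Allee effect*: as
disturbance (notably bleaching-driven mortality) thins a population, the
distance between surviving gravid colonies grows and per-colony
fertilization success falls, potentially tipping into reproductive
failure. This package estimates that relationship from colony-level field
data — mapped colony positions and areas, per-night spawn observations,
and fertilized/total egg counts per colony-night — and condenses it into
a site-level metric suitable for monitoring and restoration targets.

## Data model

Three tables drive everything (`read_colony_table()`,
`read_spawn_events()`, `read_fert_samples()`): mapped colonies (planar
coordinates in metres in an arbitrary local frame, planar area in m²,
gravidity, depth class), spawn events (night, release minute with minute
1 the first observed release of that night, extent of spawning, observer)
and fertilization samples (fertilized count out of eggs scored, optional
damage-scored subset, optional dispersal group). Coordinates are treated
as planar because the method operates at a scale of tens of metres, where
geodesy is irrelevant. Tables are comma-delimited UTF-8 with a header;
booleans are written `true`/`false` and missing optional fields are left
empty.

## Neighbourhood metrics

For each focal colony, `compute_all_metrics()` derives:

* **nearest gravid neighbour** `nn` (m) — the minimum centre-to-centre
  distance to any other gravid colony. Distances are centre-to-centre
  because only planar area, not outline, is recorded. A colony with no
  other gravid colony on the map raises an error rather than returning an
  infinite value: its `nn` is undefined.
* **density** within 2, 5, 10 m — counts of other gravid colonies with
  distance ≤ r. The boundary is closed (a neighbour at exactly r counts),
  a deterministic reading of "within a radius".
* **distance-weighted gravid area** within 10 m — Σ areaⱼ·exp(−dⱼ/λ),
  with decay length λ defaulting to 5 m (half the window). The
  exponential down-weighting represents sperm dilution with distance; the
  decay length is a modelling choice, exposed in `run_config()` and
  recorded in the metrics metadata sidecar, since no single value is
  canonical. The focal colony's own area is excluded, by analogy with
  nearest *neighbour*.

All three are validated in the test suite against naive double-loop
oracles and are invariant under rigid motions of the map.

## The fertilization model

Counts of fertilized eggs are overdispersed relative to binomial — eggs
within a sample share a colony, a night and a patch of water — so the
response is modelled as beta-binomial in the mean–precision
parameterisation (`betabinom_logpmf()`): the per-egg success probability
is Beta(μφ, (1−μ)φ), giving mean μ and overdispersion that vanishes as
φ → ∞. The response is the *count pair* (k, n), never a percentage: a
proportion carries no information about its denominator.

The linear predictor on logit(μ) contains one proximity metric, a night-2
indicator, and optionally: release time as a quadratic nested within
night (separate time and time² slopes per night), depth class, or
dispersal group (`model_spec()`, `build_design()`). Release time is
converted to minutes since the first release of the night, centred at the
per-night mean and scaled by the per-night SD before squaring — centring
is a conditioning choice for the optimiser (the quadratic would otherwise
be nearly collinear with its linear term) and is stored with the fit so
predictions reuse the identical scaling. When a night's releases all fall
in one minute the scale degenerates and is set to 1, leaving a zero
column rather than an error. Categorical terms use first-level reference
coding.

### Estimation

`fit_betabinom_glm()` maximises the log-likelihood over the coefficients
and log φ with BFGS (numeric gradients, relative tolerance 1e-10 on the
objective, up to three jittered restarts on reported non-convergence).
Standard errors come from the inverse observed information (numerical
Hessian at the optimum) and Wald p-values from the normal reference —
matching the conventional reporting for this model class. The AIC is
2k − 2logL with k counting every estimated parameter, including φ.

Two numerical guards matter in practice:

* **log φ is soft-bounded at ±15.** Beyond φ ≈ 3×10⁶ the beta-binomial is
  numerically indistinguishable from the binomial at realistic egg
  counts, while the `lgamma` differences in the pmf lose precision and
  can destabilise the search; without the bound, near-binomial data can
  send the optimiser into a region where the likelihood surface is
  numerical noise.
* **The colony random intercept is reported honestly at its boundary.**
  With `random_intercept = TRUE` a Gaussian colony intercept is
  integrated out by adaptive Gauss–Hermite quadrature (15 nodes, centred
  at each colony's conditional mode found by Newton steps and scaled by
  the curvature there; nodes from `pracma::gaussHermite`). The profile
  likelihood in log σ flattens as σ → 0; after the interior search the
  fit is compared against the σ = 0 limit (the fixed-effects likelihood)
  and, when the boundary is at least as good, the variance is reported as
  exactly 0 with a note. When a variance component is truly absent, its
  ML estimate sits at this boundary in roughly half of replicate
  datasets and at a small positive value otherwise — both outcomes are
  correct ML behaviour, and the test suite verifies both against
  glmmTMB on identical data (the quadrature log-likelihood is never below
  glmmTMB's Laplace approximation). Because boundary variances are
  common, random-intercept fits report the AIC both counting
  (`aic`) and not counting (`aic_no_re`) the variance parameter.

`fit_binomial_glm()` provides the φ → ∞ limit through `stats::glm` in the
same result shape; it backs the spawning-intensity and gamete-damage
night comparisons, where two-row designs leave no room to estimate
overdispersion. `compare_models()` fits a candidate list (default: the
five proximity metrics, each with the night effect) and ranks by AIC,
flagging but retaining non-converged fits. Randomised-quantile residuals
(`quantile_residuals()`) are emitted as a table for external QQ
inspection; plotting itself is out of scope.

## Spawning synchrony

`build_pairs()` forms every unordered same-night pair of spawning
colonies with its absolute release-minute difference, intercolony
distance and an indicator for whether both times came from the same
observer (dive computers display whole minutes, so cross-observer pairs
carry extra timing error; sub-minute interpolation is deliberately not
attempted). `fit_synchrony_model()` fits
`abs_dt ~ distance + same_observer + night` by least squares, pooling
nights with an indicator while also reporting per-night slopes, and drops
the observer term with a note when it is constant.

Pairs sharing a colony are not independent, so the least-squares p-value
is optimistic. The function therefore also reports a permutation p-value:
spawn times are shuffled across colonies *within* each night (9,999
permutations by default, seeded) and the distance partial slope is
recomputed. Because the permutation only moves times, the distance column
residualised on the remaining covariates is fixed, and each permutation
reduces to one inner product — the exact least-squares partial slope at
negligible cost. Both p-values are reported, clearly labelled; the test
suite verifies the permutation test holds its nominal 5% type-I error
(rate within [0.03, 0.07] over 1,000 null simulations).

## The Allee metric

`fit_cubic()` evaluates the fitted night-1 mean curve (percent scale)
over an even nearest-neighbour grid — default 0–20 m in 0.1 m steps,
matching the range of separations over which such data are informative —
and fits a cubic by ordinary least squares. The cubic is a portable
summary: the potential metric can be applied with four coefficients and a
tape measure. `F0` is defined as the curve at zero separation (its
constant term). Outside its natural range the cubic is clamped to
[0, 100]; with the reference coefficients the tail goes slightly negative
beyond ~23 m, and the clamp is part of the documented evaluation rule
(`eval_curve()`). Grid-step insensitivity (0.1 vs 0.05 m) is tested to
1e-3 on every coefficient.

`fertilization_potential()` averages, over colonies, each colony's
predicted success at its own `nn` relative to `F0`, times 100 — the
proportional area under the sorted per-colony success profile. It is
order-invariant, scales correctly under duplication, and can never
increase when any single colony becomes more isolated (tested by random
perturbation). Both evaluation routes are exposed — through the cubic
(default, for parity with the portable summary) and directly through the
fitted beta-binomial mean — and the pipeline reports both; on study-like
configurations they agree within one percentage point.
`threshold_metric()` offers the alternative summary (percentage of
colonies meeting a chosen success threshold), whose difficulty — choosing
the threshold — is left to the user.

## The synthetic-data generator

`gen_params()` fixes the study conditions the package is validated under:
a 100 m × 60 m site, 210 mapped colonies, 26 focal gravid colonies,
two consecutive nights, 200 eggs scored per sample, true coefficients
β₀ = −0.849, β_nn = −0.16, β_night2 = −1.01 on the logit scale with
precision φ = 8, per-night release probabilities 0.74/0.77, extensive-
spawning probabilities 0.35/0.64, a 3:1 night-1:night-2 damage-probability
ratio (0.30/0.10), and a synchrony decay of 0.15 min·m⁻¹ (3 minutes over
20 m). The clustered point process (8 parents, 2 m Gaussian spread, 15%
uniform scatter, 35% gravid) was chosen so nearest-neighbour separations
of focal colonies span roughly 0.2–19 m, the envelope over which the
method is meant to operate; `make_study_fixture()` additionally nudges
gravid colonies into exactly that envelope so fixtures are always valid.
Colony areas are log-normal with median 0.2 m² — an invented
distribution, as only its existence, not its form, is observable from the
kind of survey emulated.

Spawn times come from a spatially correlated Gaussian field with
exponential correlation. If two colonies' times are bivariate normal with
marginal SD σ and correlation ρ(d), then E|Δt| = 2σ√((1−ρ(d))/π); the
correlation range is calibrated, per simulated site, so the least-squares
slope of that curve *over the site's actual pair distances* equals the
target 0.15 min·m⁻¹. Calibrating over the realized distances rather than
a nominal 0–20 m window is essential: pairs at a 100 × 60 m site extend
to ~100 m, where the field decorrelates and E|Δt| saturates, and a
0–20 m calibration would produce fitted slopes an order of magnitude
below target. The default marginal SD of 15 min is the smallest round
value for which the target slope is achievable at all (the saturation
ceiling of E|Δt| is 2σ/√π). Times are discretised to whole minutes with
the earliest release as minute 1, and observers are assigned by five
spatial transects, mirroring how such data are collected.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: hydrodynamics (wind-driven transport,
slick formation, turbulence), egg buoyancy and drift, gamete aging over
the spawning window, colony-size-dependent gamete output, clonality, and
any spatial structure in gravidity. The night-2 fertilization drop is a
fixed offset, not an emergent consequence of weather.

## Validation design and problem sizes

Stochastic checks in the test suite run at sizes chosen to give
comfortable Monte-Carlo margins while keeping the default run fast:
parameter recovery regenerates 200 complete datasets (fresh map,
schedule and counts each time — the full generator-to-estimate path) and
requires each mean estimate within two Monte-Carlo standard errors of
truth with 95% Wald coverage inside [0.90, 0.98]; the permutation test's
size is estimated from 1,000 null datasets at 499 permutations each;
oracle comparisons (grid searches, enumeration, double loops, glmmTMB
cross-fits) run at small n where the oracle is exact. Every stochastic
test fixes its seed, so the suite is deterministic.

Small-sample note: at 26 colonies × 2 nights, ML estimates of this model
carry a genuine away-from-zero bias of a few hundredths on the logit
scale (largest on the night-2 offset) and φ is overestimated by a few
percent — visible if the recovery experiment is rerun at many times the
replicate count, and consistent with standard ML small-sample behaviour.
The package reports plain ML, as is conventional; users needing
bias-reduced estimates at these sample sizes should treat coefficient
magnitudes near their standard errors with care.

## Known limitations

* The exponential weighting of the area metric and its λ = 5 m default
  are assumptions; conclusions that hinge on the weighted-area metric
  should be checked across λ.
* The fertilization-distance curve is estimated from two nights at one
  site; the cubic coefficients shipped as defaults in `allee_curve()`
  describe that reference population, not corals generally.
* The potential metric conditions on the observed spatial configuration;
  it does not model future mortality, recruitment, or larval exchange.
* The permutation test addresses pair non-independence for the synchrony
  slope; the beta-binomial model addresses within-sample correlation via
  φ, but unmodelled between-colony spatial correlation in fertilization
  would make reported standard errors optimistic.
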