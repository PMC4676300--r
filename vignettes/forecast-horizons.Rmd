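---
title: "Forecast horizons: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecast horizons: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the quantities it
computes, the simulators behind its case studies, the numerical decisions
that shape the estimates, and what the synthetic-data tests do and do not
establish about real data.

## 1. Proficiency curves and horizons

A forecast is judged against the truth by a *proficiency* measure with a
declared orientation. For continuous series the package slides a window of
`window_length` points (default 10) in steps of `step` (default 1) along
the shared time axis and computes, per window and forecast replicate,
Pearson correlation, an error statistic (bias, MSE, RMSE, MAE) on the
residuals, or R². The distance assigned to a window is its centre — the
mean of its time points — which keeps curves symmetric under time reversal;
the window length and step are never implied by theory and must be chosen
by the analyst (they are arguments everywhere). Windows in which either
series is constant leave the metric undefined; such points are stored as
`NA` and *skipped* by every estimator, never imputed, because silently
substituting zero would bias horizons toward the threshold.

R² follows the squared-correlation convention (observed vs predicted) by
default; the `1 - SSres/SStot` convention, which also penalises bias, is
available via `convention = "ss"` with negative values truncated at zero so
the curve stays on its documented [0, 1] scale.

The **horizon** of a curve is its first threshold crossing in the stated
direction, linearly interpolated between adjacent points (a step rule is
available). A curve starting on the crossed side has horizon 0; a curve
that never crosses has horizon ∞ — the fully deterministic,
perfectly-parameterised forecast. Only the first crossing defines the
horizon; later re-crossings are reported by `detect_blind_spots()`, whose
"bad" and "good" intervals partition the curve's support exactly (shared
interpolated endpoints). For curves that improve with distance — the
phylogenetic pipeline — the crossing direction `rises_above` marks where
the useful region *begins*.

Replicate curves yield a horizon distribution. Infinite horizons are
ranked above all finite values; percentiles use linear interpolation
between order statistics (type 7), and any percentile whose interpolation
bracket touches an infinite order statistic is reported as ∞ — hence the
median is infinite as soon as half the mass is. The mean is reported over
finite values only, with the infinite count alongside, because a single
non-crossing replicate would otherwise destroy the summary. The default
band is the interquartile range; a deliberately narrow 55th–65th band is
available by argument for dense plots. Horizons can be summarised either
per replicate (then aggregated) or on the replicate-averaged curve; the
two do not coincide in general — crossing and averaging do not commute —
so both are computed and the choice is explicit.

`fit_decay_curve_horizon()` serves sparse or noisy curves: least-squares
fits of `a·exp(-d/τ)` (via Levenberg–Marquardt with positivity bounds and
log-linear starting values), a decreasing sigmoid `a/(1+exp((d-m)/s))`, or
a monotone Hermite interpolating spline. The crossing is solved in closed
form on the fitted curve; the 95% interval comes from intersecting the
delta-method confidence envelope of the fitted values with the threshold.
Crossings are certified only within the observed distance range — a fitted
curve that stays above the threshold over the data reports ∞ rather than an
extrapolated crossing. How the original curve-fit intervals in this
literature were propagated to horizon ranges is not recorded anywhere we
know of; envelope intersection is our choice and may differ from other
implementations. In repeated simulation (200 noisy exponential curves,
σ = 0.05, 30 points) the interval covers the generating crossing in ≳95%
of runs — the package's test suite recomputes this.

## 2. The Lyapunov route

For a deterministic one-dimensional map, predictability is governed by the
largest Lyapunov exponent λ. `twin_divergence()` iterates two trajectories
δ₀ apart and records ln|δ_t|; `estimate_le()` fits a line to the
pre-saturation part. Saturation is declared at the first step where the
separation exceeds 25% of the sampled attractor range, because exponential
growth of the separation is only meaningful while the separation is small
compared to the attractor; at least five points must precede it. The
independent route `le_orbit_average()` averages ln|f′(x_t)| along the
orbit; the two agree within 0.05 on the chaotic logistic maps the tests
exercise, and the logistic map at growth rate 4 recovers its exact value
ln 2. The predictability time `T_p = ln(Δ/δ₀)/λ` is algebra, not
estimation; its logarithmic dependence on δ₀ (halving δ₀ buys exactly
ln 2/λ time steps) is asserted exactly in the tests. A non-positive λ gives
an infinite horizon. Only the largest exponent is treated; full
Benettin/QR spectra for multidimensional systems are out of scope.

## 3. The chaotic Ricker experiment

Truth follows `N(t+1) = N(t)·exp(r(1 − N(t)/K(t)))` with `r = 3` (well
inside the chaotic regime; the one-dimensional map's orbit-averaged λ is
positive), `K₀ = 100`, `N₀ = K₀/2`, 100 generations. The carrying capacity
may drift linearly, `K(t) = K₀ + K_step·t` (a step change at mid-run is
available behind `k_mode = "step"`, since "rate of change" admits either
reading). Demographic stochasticity, when enabled, replaces the
deterministic update by a Poisson draw with that mean, the canonical
discrete-birth noise; it makes the population integer-valued and `N = 0`
absorbing, and it is a property of the *truth* only — the forecaster's
model is always deterministic, which is precisely the model-inadequacy
framing of the experiment.

The forecaster's uncertainty is a coefficient of variation per parameter:
draws are normal with mean at the true value and SD = CV·value, truncated
at zero by resampling for `r` and `N₀` (capped retries), untruncated for
`K_step`. A stochastic truth is re-simulated per replicate by default
(`resimulate_truth = FALSE` holds one realisation fixed). Proficiency is
windowed correlation; the experiment returns the aggregated curve, the
horizon distribution and the mean-curve horizon, and is bit-reproducible
from (configs, seed).

At the study scale used throughout (9 uncertainty cells, CV ∈
{10⁻³, 10⁻², 10⁻¹}² on r and N₀, 200 replicates per cell, threshold 0.5)
the tests verify: proficiency starts near 1 and falls below 0.1 within 30
generations in every cell; medians decline as any single CV grows; and a
Poisson-noisy truth never has a farther median horizon than its paired
deterministic truth. Ordering assertions on medians are made at the
curve's grid resolution (one generation): crossings are interpolated
between windows one generation apart, and sub-grid differences between
medians are interpolation noise, not signal.

## 4. The eco-evolutionary experiment

The community model is the standard Gaussian-kernel trait-based
competition model: species *i* has trait `x_i` on a resource axis,
carrying capacity
`K_i(t) = K_max·exp(κ·θ_t − (x_i − θ_t)²/(2σ_K²))`,
competition `α_ij = exp(−(x_i − x_j)²/(2σ_α²))`, Ricker-form abundance
updates, and (when evolution is on) deterministic trait dynamics climbing
the per-capita growth gradient at rate `h` — a quantitative-genetics
reading of heritable trait change; mutation-driven stochastic evolution is
out of scope. The environment θ_t is a stationary AR(1) series (marginal
SD `sd_env = 0.5`, lag-1 autocorrelation `rho = 0.7`, i.e. reddened as
field environments typically are).

Two design points deserve emphasis, because the verbal description this
model reconstructs underdetermines them and both turned out to matter:

* **The environment moves productivity, not just the optimum.** With a
  pure position shift of the resource distribution, a community that tiles
  the axis compensates almost perfectly: total biomass has a nearly
  cancelled first-order response to θ, so under environmental uncertainty
  its correlation proficiency is pure noise and aggregate variables would
  *look* less predictable than species — an artefact of the symmetric
  kernel, not ecology. The log-linear productivity coupling
  (`env_K_coupling`, default κ = 1.5) lets good years carry more resource,
  giving biomass the smooth first-order environmental response real
  aggregate variables have.
* **The case-study community starts clustered** (8 species on
  [−0.6, 0.6]) so that competition drives a deterministic character
  displacement — an adaptive radiation — in the evolving truth. This makes
  the evolution effect on forecasts robust to the particular environmental
  realisation; with widely spread traits the community sits near its
  evolutionary equilibrium and whether evolution affects a given species
  depends on the environmental path, which makes horizons erratic across
  seeds.

The truth is one history (evolving or not, per flag); forecasts never
evolve and see `θ̂ = θ + σ_u·Z`, with one standard-normal series Z per
replicate scaled by each uncertainty level in turn — common random
numbers, so level comparisons are paired; marginally each perturbation is
exactly the white-noise corruption of `perturb_environment()`. At σ_u = 0
all replicates coincide with the truth's environment, so summaries have
zero width, and with evolution off the forecast is bit-identical to the
truth: an exactly infinite horizon. The focal species is the community
dominant (largest mean true abundance) — "one of the species" must be
chosen somehow, and the dominant is the natural reporting choice and
cannot go extinct in the truth. A replicate whose proficiency curve has
fewer than two defined points (a defunct forecast) scores horizon 0.

At the tested scale (σ_u ∈ {0, 0.1, 0.25}, 100 replicates, 300
generations, threshold 0.5) the suite verifies the level-of-organisation
pattern: the median horizon for total biomass is at least that for focal
abundance at every uncertainty level, and both decline as σ_u grows (again
at one-generation resolution).

## 5. Spatial and phylogenetic horizons

**Distance decay.** All site pairs' similarities — Sørensen on presence
sets, or Pearson correlation of square-root abundances — are binned by
geographic distance (equal-width bins over the observed range; empty bins
are `NA`) and the per-bin mean forms a proficiency curve in km. Planar
coordinates use Euclidean distance; longitude/latitude inputs use the
haversine. The spatial horizon is the falls-below crossing.

**Host use.** A binomial GLM (IRLS, convergence 10⁻⁸, 50 iterations)
models use of a candidate plant as a function of the herbivore's host
breadth (raw count by default; log behind a flag) and the plant's minimum
patristic distance to another known host — "distance to a known host" is
operationalised as the minimum, the most conservative aggregation.
Complete separation is an error that recommends the ridge fallback, a
Newton-IRLS fit with an L2 penalty of 10⁻⁶. Predictions are sliced into 12
patristic-distance bands (equal record counts by default, protecting the
per-slice class balance; equal width available) and AUC — the Mann-Whitney
rank statistic, ties counted ½ — is computed per slice. Slices lacking
both classes are `NA` and skipped. The phylogenetic horizon is the
rises-above crossing: host-use proficiency *improves* with distance.
Whether the original slice construction weighted fits by slice size is not
recorded; we compare raw slice curves, unweighted.

## 6. What the synthetic generators emulate — and what they do not

`gen_spatial_communities()` gives each species a range centre and an
exponential random range radius with mean `decay_scale_km`; it occupies
every site inside the radius, so marginal occupancy declines exponentially
with site-centre distance while ranges stay spatially *coherent*. The
coherence is essential: independent per-site occupancy coins cap
similarity at the mean-field level regardless of distance, and no decay
curve worth the name emerges. Abundances are log-normal around a mean
decaying from the centre. The tests verify limit behaviour (similarity
slope ~0 when the scale vastly exceeds the arena; far-bin < near-bin
similarity in ≥95% of seeds at small scales) and that the fitted spatial
horizon increases with the generating scale (150/300/600 km, 50 seeds,
correlation threshold 0.7).

`gen_yule_tree()` produces pure-birth trees at 0.03 speciations per
million years, matching 100–200 MY plant-family depths.
`gen_host_use_table()` assigns each herbivore a breadth (1 + Poisson,
mean 8) and seed hosts clustered within one clade with probability 0.8 —
the family-level host ranges typical of herbivorous insects — then draws
use from a logistic law in breadth and minimum patristic distance
(β = (1, 0.4, −0.03)) *plus an idiosyncratic logit noise whose SD decays
with distance* (5·exp(−d/60 MY)). The idiosyncrasy term is the fixture's
key structural assumption: whether an insect eats a close relative of its
hosts depends on unmeasured plant traits, while distant plants are
predictably avoided. It is also what makes slice-AUC *rise* with distance:
for a correctly specified model, in-slice AUC tracks only the within-slice
spread of the linear predictor, so a pure logistic law yields flat slice
curves — near-distance unpredictability, not the distance coefficient,
creates the rising profile. With the noise off, the generating
coefficients are recovered by the GLM within standard errors (the tests
fit at n = 5000).

Scales: the rising-AUC property is demonstrated at ~6000 records (40
herbivores, 150 taxa; Spearman of slice midpoint vs AUC positive in ≥90%
of 50 seeds). The data-reduction comparison — refitting on a random third
of the records moves the rising crossing to a coarser distance in ≥80% of
seeds — is demonstrated at a deliberately lean scale (12 herbivores, 40
taxa): with thousands of records a third still saturates a 3-parameter
GLM and the effect disappears. That observation is itself informative:
data reduction only coarsens phylogenetic forecasts when data, not model
capacity, is limiting.

None of the generators emulates spatial autocorrelation of abundances
within ranges, observation error, phylogenetic signal in herbivore
identity, or non-equilibrium range dynamics. Passing tests therefore show
that the estimators recover known structure of these forms, not that real
survey or interaction data satisfy the generators' assumptions.

## 7. Numerical choices and degenerate inputs

* Crossings: linear interpolation between adjacent defined points;
  exact-threshold points count as not-yet-crossed (measure-zero ties).
* Zero-variance windows, empty distance bins, single-class slices: `NA`,
  skipped, never interpolated across.
* All pairs at a single distance (e.g. two sites): a single-point curve is
  returned; horizon estimation requires two points and refuses it.
* Quantile slice edges tied at a repeated distance are collapsed at
  relative tolerance 10⁻⁹ (the true maximum is retained so every record
  falls in a slice).
* Infinite horizons serialise to JSON as the string `"inf"` plus an
  `is_infinite` flag; reports carry seed and a config digest.
* Every stochastic routine takes an explicit seed and is a pure function
  of (arguments, seed).

## 8. Known limitations

Probabilistic-forecast scores (CRPS, log score) and multivariate/combined
horizons are out of scope. The eco-evolutionary model is a reconstruction
from a verbal description; its parameter values are defensible, not
canonical, and every one is exposed in `ecoevo_config()`. Horizon medians
are step-ish functionals of noisy curves: comparisons finer than the curve
grid are not meaningful, which is why ordering tests use one-generation
tolerance. The Lyapunov tools address one-dimensional deterministic maps;
estimating exponents from observed noisy series (attractor
reconstruction) is deliberately not provided.
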