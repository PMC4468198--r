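---
title: "Temperature-driven phenology, pest risk indices and yield-loss projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-driven phenology, pest risk indices and yield-loss projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorisk)
```

phenorisk models how temperature alone shapes the distribution, abundance
and crop impact of insect pests — the motivating system being maize stem
borers and their larval parasitoids along East African mountain gradients,
where a few hundred metres of altitude stand in for degrees of warming.
This vignette is the package's own account of the science: the models, the
choices that were genuinely open, and what the synthetic test-bed does and
does not show.

## The phenology model

A species is a `species_model`: three immature stages (egg, larva, pupa),
each with three temperature responses, plus an adult longevity model and a
fecundity model.  All temperatures are degrees Celsius; all rates are per
day; there is no humidity, rainfall, diapause, density dependence or
migration anywhere in the package — the model is deliberately
temperature-pure.

* **Development rate** (`development_rate()`): the classical Logan curve
  `psi * (exp(rho (t - t_base)) - exp(rho (t_max - t_base) - (t_max - t)/delta))`,
  clamped at zero below `t_base` and at/above `t_max`.  It rises roughly
  exponentially, peaks a few degrees below the lethal maximum, and
  collapses over the width `delta`.
* **Stage mortality** (`stage_mortality()`): a second-order exponential
  polynomial `min(1, exp(b0 + b1 t + b2 t^2))`, interpreted as
  *whole-stage* mortality at constant temperature.
* **Development-time variability** (`sample_dev_multiplier()`): individual
  spread enters as one multiplier per stage per individual, the inverse
  CDF of a logit (eggs, larvae) or complementary log-log (pupae) family on
  log-normalised time.  The intercept is fixed at zero so the logit median
  is exactly 1 and the single slope `beta` controls spread — an
  identifiable, directly testable anchor.  The cloglog family is
  asymmetric; its median is `(ln 2)^(1/beta)`, which the tests use as the
  analytic anchor for pupal durations.
* **Adult longevity**: either the three-parameter Stinner logistic
  `c_max / (1 + exp(k1 + k2 t))` or the Hilbert–Logan senescence rate
  (lifespan = 1/rate at constant temperature); exactly one family per
  species, as a tagged choice.
* **Fecundity**: a quadratic lifetime total in temperature, distributed
  over normalised adult age by a gamma CDF renormalised to the unit
  interval (`oviposition_fraction()` over any partition of [0, 1] sums to
  1 to 1e-12).

The named model families are fixed in their canonical published forms;
their parameters are user inputs (YAML species files, validated on read).
Fitting these curves to raw laboratory life tables is out of scope.

## Weather driver

Daily station records (tmin, tmax) on a fixed 365-day calendar drive
everything.  Sub-daily temperatures are inferred by a single full-period
cosine with the maximum pinned at 14:00 and the minimum at 02:00
(`hourly_temperatures()`); the mean of the 24 hourly values equals the
daily mean exactly.  The phase is the simplest anchored choice —
sunrise-dependent phases are out of scope — and is documented so results
are reproducible.  Future climates are additive monthly deltas
(`apply_scenario()`), invertible by negation; leap days are ignored
because all indices are annual.

## Cohort simulation and life-table parameters

`simulate_cohort()` follows `n_individuals` female eggs individually:

1. **Rate summation.** Development accumulates as
   `sum(rate(T_step) * dt) / multiplier` until it reaches 1, at hourly
   (default) or daily-mean resolution.  At constant temperature with no
   variability, stage duration is exactly `1/rate` — the package's most
   important exactness anchor.
2. **Mortality.** Whole-stage mortality `m`, evaluated at the running mean
   stage temperature, is converted to per-step survival
   `(1 - m)^ddev` where `ddev` is the fraction of the stage completed that
   step.  Cumulative survival over a completed stage at constant
   temperature is then exactly `1 - m`, so the lab-measured quantity is
   recoverable by construction.
3. **Adults.** Adult lifespan is deterministic given temperatures
   (Stinner longevity re-evaluated at the running mean adult temperature,
   or senescence-rate summation to 1).  Lifetime female eggs are
   `total_fecundity(mean adult T) * sex_ratio`, spread over adult days by
   the gamma age profile.

The cohort is tabulated on a daily age grid as the standard female
`l_x`/`m_x` schedule, and the five classical parameters follow:
`R0 = sum(lx mx)`, `T = sum(x lx mx)/R0`, `rm` solving the Euler–Lotka
renewal equation `sum(exp(-rm x) lx mx) = 1` (safeguarded Newton with a
maintained bisection bracket, residual < 1e-10, cross-checked against an
independent bisection oracle), `lambda = exp(rm)`, `DT = ln 2 / rm`.
Because the cohort tracks females and `sex_ratio` converts eggs to female
eggs, a no-mortality cohort with fecundity 100 and sex ratio 0.5 has
`R0 = 50` exactly.  Extinction (no reproduction) is data — a flagged
result with `R0 = 0` and `rm = NA` — never an exception, because the
mapping stage must be able to interpolate over lethal locations.

One modelling choice deserves emphasis: variability is *one multiplier per
stage per individual*, not a daily re-draw.  This makes the simulated
median duration equal the family's analytic median of `1/rate`, which the
tests verify within three Monte-Carlo standard errors at n = 2000.

## Risk indices

Three annual indices, each given a precise algebraic definition matching
its verbal gloss:

* **ERI** (establishment): the annual mean over days of the product of
  daily stage survivals at the daily mean temperature — in [0, 1],
  monotone non-increasing under any pointwise mortality increase.
* **GI** (generations/year): `365 / mean(generation time)` over 12 cohorts
  launched on the first day of each month (weather wrapping), non-extinct
  launches only; launch k is seeded `seed + k`.
* **AI** (activity): `sum(max(rm_floor, rm(daily mean))) / ln 10` — the
  decimal orders of magnitude of annual population growth.  `rm` comes
  from a precomputed constant-temperature profile (`rm_profile()`,
  piecewise-linear in temperature) rather than 365 daily simulations; the
  floor (default -0.1/day) stops a few lethal days from dominating the
  annual sum, and extinct profile nodes carry a -0.5/day sentinel.

ERI and AI are driven by daily means for speed; GI uses the full
simulator.  This asymmetry is deliberate and documented.  Host–parasitoid
*synchrony* is simply the signed ERI difference (host minus parasitoid),
elementwise over stations or grids.

## Spatial interpolation

Station indices are interpolated over a DEM by an exact thin-plate spline
(`fit_tps()`): kernel `r^2 log r` in (x, y) plus an affine trend with
station elevation as a linear covariate — the most common reading of a
DEM used "as co-variable"; a full 3-D spline is out of scope.  Smoothing
defaults to 0 (exact interpolation) because transects have only ~6
stations.  Numerically the system is solved in centred, rescaled
coordinates: the raw system with metre coordinates is singular to working
precision, and rescaling preserves exactness, the orthogonality
constraints on the kernel weights, affine reproduction and translation
invariance (all tested).  Grids are ESRI ASCII files with a pinned
dialect (lower-case keywords on write, case-insensitive read, 6
significant digits); point sampling is nearest-cell with a round-half-up
tie-break (ties go east/north); scenario change is a cellwise grid
difference with nodata propagation.

## Yield loss

Each transect splits into four agro-climatic altitude zones (lowland
tropical < 1000 m, dry mid altitude 1000–1300, moist transitional
1300–1600, highland tropics > 1600; bands lower-inclusive,
upper-exclusive, top zone unbounded).  Observed percent losses per zone
are exogenous inputs.  The model is ordinary least squares of loss on
zone-mean activity index, `Y = beta0 + beta1 A`; future losses re-use the
fitted line with future AI.  Predictions are never clamped (published
analyses report raw linear predictions), and with only four zones the
residual degrees of freedom are 2 — the fit always logs a low-n caution.
Note that ±2 standard errors covers only ~82% of a t distribution at 2
df, so the package's replicate-recovery property test uses a 12-zone
synthetic design (df = 10, coverage ~93%) where a ≥90% recovery rate is
actually attainable.

## The synthetic test-bed

`make_transect()` emulates a 6-station altitudinal transect (700–1800 m):
a single annual temperature harmonic (amplitude 2 °C, peak mid-February),
a constant 10 °C diurnal range, i.i.d. daily noise (sd 1 °C), a standard
-6.5 °C/km lapse rate on a 28 °C sea-level mean, and a one-sided mountain
DEM (60 × 40 cells of 500 m) whose slope is deliberately non-affine in x
so the elevation covariate is not collinear with the spline trend;
stations sit on the DEM at cells of matching elevation, with staggered y
so the trend matrix has full rank.  Passing `lapse_rate = -4.55`
reproduces the design where adjacent stations differ by ~1 °C in annual
mean.  What it does **not** emulate: the bimodal East African rainy
seasons (temperature seasonality there is mild and rainfall is out of
scope — one harmonic suffices), spatial autocorrelation of weather noise,
topographic aspect effects, or inter-annual variability.  Passing tests
therefore show internal correctness and the qualitative altitudinal
mechanics, not fidelity to any real station network.

`make_species()` ships four fixed, deterministic profiles — lowland host,
highland host and their parasitoids.  Lowland profiles have development
optima near 30 °C, highland profiles are tuned at 24 °C (their realised
rm peak lands in the mid-20s, at least 4 °C below the lowland peak);
parasitoids develop several times faster than their hosts, giving them
more generations per year.  Two design points matter:

* each profile's *mortality* optimum is a separate parameter from its
  development optimum.  The highland profiles are warm-sensitive (lowest
  immature mortality at 18–19 °C), which is what makes their
  establishment index *increase* with altitude along a 16–23.5 °C
  transect while the lowland profiles' decreases — the ecological
  contrast the profiles exist to emulate;
* highland upper lethal limits are 33–34 °C: a species that persists in
  warm lowlands does not lose all development capacity 6 °C above its
  optimum, and a narrower tolerance would make warming near the optimum
  implausibly catastrophic.

`make_scenario()` produces monthly warming deltas with mean 1.45 °C and
seasonal half-range 0.45 °C (a 1.0–1.9 °C monthly band).
`make_observed_losses()` fabricates per-zone losses from a known linear
relation plus Gaussian noise, clamped at zero; the demo pipeline's ground
truth (beta0 = -2, beta1 = 3, sd 1) is chosen so the clamp stays inactive
over the demo's zone-AI range and the generated data genuinely have the
linear structure the recovery checks assume.

## Problem sizes and numerical choices

Defaults are `n_individuals = 2000` and the hourly driver for standalone
life-table work.  The demo pipeline (`run_demo_transect()`) and the
acceptance script use 250 individuals with the daily-mean driver and a
2 °C rm-profile grid — sizes chosen so the full pipeline (four species,
six stations, two climates, mapping and regression) completes in a few
seconds while keeping Monte-Carlo error well inside the contrasts being
measured.  Other numerical anchors: Euler–Lotka to |residual| < 1e-10
inside [-1, 1] with automatic bracket expansion; rm profiles interpolate
linearly and clamp (with a warning) outside their grid hull; simulation
horizon 1095 days with still-immature individuals scored as deaths;
cohort RNG draws happen up-front in a fixed order so identical seeds give
bit-identical results regardless of control flow.

## Known limitations

Temperature is the only driver: no rainfall, humidity, diapause,
host-plant phenology, parasitism dynamics (synchrony is an index
difference, not a coupled model), immigration or density dependence.  The
cosine day and the one-multiplier variability scheme are declared
conventions, not estimates.  The thin-plate spline treats elevation as a
linear covariate only, and with ~6 stations the interpolation is
essentially a smooth altitudinal regression — fine for transects, not for
complex terrain.  Yield-loss inference at four zones has 2 degrees of
freedom; its standard errors are honest but fragile, which is why the
package logs a caution on every such fit.
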