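---
title: "Methods: seasonal dive phenology, ice break-out timing and diet mixing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal dive phenology, ice break-out timing and diet mixing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icepulse)
```

# The scientific problem

In high-latitude coastal seas, the spring sea-ice break-out releases a
short, intense near-surface phytoplankton bloom. For an air-breathing
predator such as the Weddell seal, this resource pulse propagates up the
food web: prey concentrate near the surface, and the seals' foraging depth
shallows for a few weeks in mid-summer before returning to deep winter-like
diving. `icepulse` implements the quantitative chain needed to study this
coupling from biologging and satellite data:

1. **Dive records** — time-depth-recorder (TDR) series at a 6 s sampling
   interval and 0.5 m depth resolution are zero-offset corrected, segmented
   into dives, and summarised per dive (maximum depth, duration, bottom
   phase, wiggles) and per seal-day.
2. **Feeding proxies** — prey-capture attempts are detected in 20 Hz jaw
   surge acceleration with a 0.3 g threshold; depth wiggles in the bottom
   phase serve as a second proxy.
3. **Ice phenology and advection** — sea-ice break-out at five locations
   around Ross Island is the first date whose trailing 7-day mean
   concentration drops below 50%; bloom water is assumed to advect
   along-coast to the Erebus Bay study site at one of three measured
   current velocities (6.5, 10.3, 12 km/day), arriving after
   `round(path / velocity)` whole days and blooming for ~35 days.
4. **Phenology statistics** — a penalized-spline mixed model with a random
   intercept per seal describes the seasonal depth curve; the shallowing
   period is where the fitted curve stays at or below 140 m; models using
   calendar date versus days-since-advective-arrival are compared by AIC.
5. **Diet** — whisker segments are time-stamped under a linear-growth
   assumption, tested for temporal isotope trends with a random-intercept
   model, and diet proportions are estimated with a Bayesian stable-isotope
   mixing model.

Because the raw field and satellite data are not distributed with the
package, a seeded synthetic-data generator reproduces every input stream
with machine-readable ground truth, making the full pipeline testable.

# The synthetic season and what it does (and does not) emulate

`season_scenario()` fixes the study conditions. The defaults encode the
documented season: early-summer mean maximum dive depth 233 m, a shallow
plateau at 110 m, a return to 230 m, and a *shallowing period* — the span
with trajectory at or below 140 m — lasting 24 days. Ten seals are
followed for 100 days. The trajectory is piecewise linear with 15-day
ramps; `shallow_duration` is defined as the sub-140 m span (the quantity
the analysis reports), and the 110 m plateau length is derived from it, so
truth and estimate are commensurable.

Values the source material does not fix were chosen once as field-typical
and are not tuned:

* **Dive shape.** Trapezoidal ("square-U") dives with constant 1 m/s
  descent and ascent and a flat segment whose share of dive duration is
  uniform on (0.3, 0.6). This makes bottom-phase truth unambiguous.
* **Noise structure.** Seal random intercepts (SD 15 m), seal-day noise
  (SD 20 m), dive-to-dive noise (SD 8 m): large enough that the 233 to
  110 m signal is recoverable but not trivially.
* **Dive rate.** Poisson with mean 30 dives per seal-day; surface
  intervals uniform on 1–5 min. Within-day dive rate only needs to
  separate dives cleanly.
* **Wiggles.** Planted inside the flat segment as symmetric excursions so
  that the expected rate per bottom minute equals
  `3.2589 - 0.0043 x depth`. Two design points matter. First, the
  excursion amplitude scales with depth (8% of maximum depth, at least
  2 m): with small fixed excursions, wiggly pelagic bottoms would be as
  flat (by coefficient of variation) as a true benthic bottom, and the
  benthic classifier could not work at any threshold; depth-scaled
  amplitudes match the prey-chase excursions seen in real records. Second,
  when a drawn wiggle count does not fit the flat segment, the segment is
  extended *and additional wiggles are drawn for the added bottom time*;
  truncating or merely extending would deflate realized rates on short
  shallow dives and attenuate the planted slope.
* **Benthic dives.** 1% of dives go to a stable seal-specific seabed depth
  (~380 m) with a perfectly flat bottom.
* **Capture bursts.** 4 Hz damped sinusoids, peak 0.4–0.7 g, on a 0.8 Hz
  ~0.05 g swimming oscillation plus slow swell; a 1 Hz zero-phase
  high-pass leaves the background well under 0.1 g. Captures can
  optionally be coupled to wiggles (`wiggle_coupling`) so the two feeding
  proxies correlate, as they do in real data.
* **Ice.** Cells start near 88% cover and step down to ~18% three days
  before the requested break-out day, with bounded uniform noise; the
  trailing-mean detector then recovers the requested day exactly, with a
  >4% margin against the noise. Real break-out is more gradual; the
  generator trades realism of the decline for an exact timing oracle.
* **Isotopes.** Consumers are drawn from the mixing model's own
  likelihood, so signatures, source spreads and trophic enrichment factors
  are mutually consistent, centred on a delta-15N 13.0 / delta-13C -23.2
  consumer. The shipped five-group prey table
  (`synthetic_prey_sources()`) is synthetic, patterned on a
  silverfish-dominated Ross Sea community; it is not a published dataset.

Features of real data the generator does **not** emulate: seasonal changes
in diving efficiency (the flat-fraction draw is depth- and
season-independent), haul-outs and data gaps, tidal or current advection
of the seals themselves, gradual ice decline and partial refreeze
dynamics, and nonlinear whisker growth. Passing tests therefore
demonstrate correctness of the estimators under the stated statistical
structure, not robustness to every field artefact.

# Dive processing choices

* **Zero-offset correction**: rolling 10th percentile of sub-15 m readings
  in 2 h windows, interpolated and subtracted; negative depths clamp to 0.
* **Dive definition**: surface threshold 2 m, minimum depth 10 m, minimum
  duration 30 s — typical phocid TDR settings, all configurable in
  `ip_params()`. Sampling gaps longer than twice the nominal interval
  break a record; no interpolation across dropouts.
* **Bottom phase**: first to last sample at >= 80% of maximum depth.
* **Wiggle**: a direction reversal whose shallowing and subsequent
  deepening limbs both span >= 1 m — twice the sensor resolution, which
  suppresses quantization chatter; "inflection points" is not operational
  at 0.5 m quantization.
* **Benthic rule**: maximum depth >= 0.9 x the seal's rolling 7-day
  maximum *and* bottom coefficient of variation <= 0.02. The CV is taken
  over the central 60% of the bottom phase so that the descent/ascent
  shoulders of the 80% envelope do not mask bottom flatness. The exact
  published thresholds are not available; this rule reproduces the ~1%
  benthic fraction and their temporal stability on synthetic data and is
  fully configurable. Dives with under one day of seal history are
  classified pelagic and flagged.
* **Daily means** weight each seal-day equally (the mean across seals of
  each seal's daily mean), not each dive.

# Ice phenology and advection geometry

The break-out detector uses a *trailing* 7-day window (inclusive of the
current day) and a strict `< 50%` comparison: a trailing window makes the
date causal and reproducible on real-time data. Distances are haversine on
a 6371 km sphere (ellipsoidal corrections are sub-0.5% at these scales).
The coastal path follows the anticlockwise chain Northeast - North -
Northwest - West - Southwest - Erebus Bay, matching the direction
break-out progresses. Durations round to the *nearest* whole day with
half-up ties: with the printed coordinates this rounding uniquely
reproduces the published travel-time minima at all three velocities
(34.6 km / 6.5 = 5.33 -> 5 days; / 10.3 = 3.36 -> 3; / 12 = 2.89 -> 3,
where floor would give 2). A transient refreeze after break-out does not
reset the break-out date; the first occurrence is kept.

# The seasonal curve, its basis, and the AIC comparison

The curve model is `depth ~ s(covariate) + (1 | seal)` fitted with
`mgcv::gam`, the random intercept as an `s(, bs = "re")` smooth.
The default smooth is an **adaptive cubic P-spline** (`bs = "ad"`, basis
dimension 15). The seasonal trajectory mixes steep ramps with a flat
plateau; with a single global penalty, a small basis oversmooths the
plateau (biasing the fitted minimum ~12 m deep), while a large basis lets
the argmin wander across the plateau. The adaptive penalty resolves both,
and remains an order-4 (cubic) penalized spline. A fixed-penalty cubic
B-spline (`bs = "bs"`) is available and is substituted automatically for
small designs where the adaptive basis is unsupported.

Smoothing parameters are selected by **ML** by default, because the AIC
comparison between the calendar-date and days-since-arrival covariates
must compare marginal likelihoods across different fixed-effect
structures; REML AICs are not comparable there. `delta_aic` is defined as
`AIC(calendar) - AIC(arrival)`, positive favouring arrival alignment, and
is reported per source x velocity rather than pooled. Confidence bands are
pointwise 95% intervals.

The shallowing period is the *longest contiguous* run of evaluation points
at or below 140 m (robust to a curve dipping twice); the shallowest point
is the argmin of the fitted curve. The cross-year regression of shallowest
depth on shallowest date uses a one-tailed p for a positive slope (deeper
shallowest diving in years when it occurs later).

`period_contrasts()` defines early-deep as the first 10 observed days
before the shallowing period and late-deep as the last 10 after it, and
reports percent changes of the feeding proxy and diving efficiency across
the period boundaries. The compound change multiplies the early-to-shallow
feeding-rate and efficiency ratios: the relative increase in bottom-phase
feeding delivered per unit dive time.

# The mixing model

For consumer replicate `j` and isotope `k`,

```
x[j,k] ~ Normal( sum_s p[s] * (mu[s,k] + lambda[s,k]),
                 sum_s p[s]^2 * (omega[s,k]^2 + tau[s,k]^2) + sigma[k]^2 )
```

with source means/SDs `mu/omega`, TEF means/SDs `lambda/tau`, diet
proportions `p ~ Dirichlet(alpha)` (uniform `alpha = 1` by default; no
prior is stated in the source material) and half-normal residual SDs. The
sampler is random-walk Metropolis on the additive log-ratio transform of
the simplex, with the Dirichlet prior and ALR Jacobian combining to
`sum(alpha * log p)`. During warm-up the proposal adapts both a global
step (targeting ~25% acceptance) and its *shape* from the empirical
covariance of warm-up draws — the likelihood often carries a collinearity
ridge between isotopically similar sources that a spherical proposal
traverses slowly. Four chains of 5,000 post-warm-up draws (2,000 warm-up)
run in about a second; convergence is reported as split-chain potential
scale reduction, with results flagged (never silently returned) above
1.05.

Consumers are pooled (per-seal whisker means as replicates of one
consumer) by default, matching the averaging described for the study
design; per-seal fits can be run by subsetting. Whisker time-stamping uses
a linear growth assumption isolated in `assign_segment_dates()` so a
nonlinear curve can be swapped in.

# Numerical and degenerate-input conventions

* Depth quantization to 0.5 m and 6 s timestamps are exact in the
  generator (every value a multiple of the resolution).
* `round_half_up()` resolves duration ties away from banker's rounding.
* A dive whose only sample at >= 80% of maximum depth is the apex has a
  zero-length bottom phase; efficiency is defined as 0 for zero-duration
  edge cases and always lies in [0, 1].
* All-deep records skip zero-offset correction with a warning; all-one-date
  designs error as rank-deficient; ice windows containing gaps are skipped
  with a warning.
* Every generator and the MCMC sampler are deterministic given a seed; the
  pipeline derives all stage seeds from the single config seed.

# Problem sizes used in the test-suite

The packaged checks run the estimators at sizes chosen to exercise the
statistical structure while staying desk-scale: oracle equivalence on
1,000 randomized small instances per detector; parameter recovery on 100
seeded replicates of the default 10-seal, 100-day season (dive-level
ground truth feeding the summary-and-fit estimators, with the raw-signal
path verified exactly against oracles and end-to-end on smaller
deployments); the covariate comparison on 100 two-year replicates with a
20-day arrival spread; mixing-model calibration on 50 simulations from its
own likelihood. Full-signal runs (the raw 6 s depth series) are used in
the end-to-end pipeline and determinism checks on deployments of a few
seal-weeks.

# Known limitations

* The benthic/pelagic rule is a documented stand-in for unavailable
  published thresholds; treat absolute benthic fractions on real data with
  care and calibrate `benthic_depth_ratio` / `benthic_cv_max`.
* The along-coast path is a five-waypoint chain; the true advective path
  is longer and bathymetry-steered, so only travel-time *minima* are
  geometric facts of the printed coordinates.
* The mixing model has no concentration dependence or isotopic routing,
  and diet proportions for isotopically similar sources are intrinsically
  weakly identified (wide credible intervals are the honest output).
* Gridded ice input is long-format CSV; NetCDF sources should be exported
  to CSV upstream.
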