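# icepulse

Analysis pipeline for studying how the seasonal diving depth of an
air-breathing marine predator tracks sea-ice break-out and the advected
phytoplankton resource pulse. Written for movement ecologists working with
Weddell seal (or similar pinniped) biologging data in ice-covered seas, it
covers the full chain from raw instrument records to the statistics the
field reports:

* **Dive processing** — zero-offset correction of time-depth-recorder
  series (6 s sampling, 0.5 m resolution), dive detection, per-dive
  metrics (maximum depth, duration, bottom phase at >= 80% of maximum
  depth, wiggle counts), benthic/pelagic classification, and per-seal-day
  summaries.
* **Prey-capture detection** — zero-phase high-pass filtering of 20 Hz
  jaw surge acceleration and thresholding at 0.3 g, with jaw-rate /
  wiggle-rate correlation.
* **Ice phenology & advection timing** — per-cell break-out date (first
  trailing 7-day mean concentration `< 50%`), along-coast great-circle
  path distances from five Ross Island source locations to the Erebus Bay
  study site, whole-day travel times at current velocities of 6.5, 10.3
  and 12 km/day, and 35-day bloom windows.
* **Seasonal phenology statistics** — a penalized-spline mixed model
  (random intercept per seal) of seal-day mean depth,

      depth_ij = f(x_ij) + b_i + e_ij,   b_i ~ N(0, s_b^2),

  with `x` either calendar day or days since advective arrival, compared
  by `dAIC = AIC(calendar) - AIC(arrival)`; extraction of the shallowing
  period (fitted depth <= 140 m), cross-year and wiggle-rate-on-depth
  regressions, and feeding/efficiency period contrasts.
* **Stable-isotope diet mixing** — whisker-segment time-stamping, isotope
  trend tests, and a Bayesian mixing model

      x_jk ~ N( sum_s p_s (mu_sk + lambda_sk),
                sum_s p_s^2 (omega_sk^2 + tau_sk^2) + sigma_k^2 ),
      p ~ Dirichlet(alpha),

  sampled by adaptive random-walk Metropolis on the simplex with
  split-chain convergence diagnostics.
* **Synthetic data** — a seeded generator reproduces every input stream
  (depth series, jaw acceleration, gridded ice, whisker isotopes) with
  machine-readable ground truth, so the whole pipeline is testable without
  field or satellite data.

See the methods vignette (`vignettes/icepulse-methods.Rmd`) for the models,
assumptions and design choices.

## Worked example

```r
library(icepulse)

# a synthetic 6-seal, 80-day deployment under the default season
sc  <- season_scenario(n_seals = 6, days = 80, seed = 11)
sim <- generate_tdr(sc, signal = FALSE)   # dive-level truth only

curve <- fit_seasonal_curve(sim$sealdays)
curve
#> Seasonal depth curve on 'day' (ML): fit range 102.5-228.7 m, AIC 4243.9

sp <- extract_shallow_period(curve)       # fitted curve <= 140 m
#> shallow period: days 40.3-66.5 (26.2 d), shallowest 102.5 m on day 49.4

daily <- daily_summaries(within(sim$truth,
          dive_class <- ifelse(benthic, "benthic", "pelagic")))$daily
wiggle_depth_regression(daily)
#> wiggle rate = -0.0041 x depth + 3.221  (R2 = 0.93)
```

The deployment was generated with a 24-day shallowing period centred on
day 53.3 at 110 m, and wiggle rates planted along
`-0.0043 x depth + 3.2589`; the fitted curve recovers the shallowest point
within ~4 days and ~8 m and the regression recovers the planted slope.

Advection geometry from the printed source coordinates:

```r
paths <- vapply(ross_island_sources()$name,
                function(s) path_km(s, "coastal"), numeric(1))
round(paths, 1)
#> Northeast     North Northwest      West Southwest
#>     161.0     135.8      85.1      59.9      34.6
sapply(c(6.5, 10.3, 12), function(v) min(advection_duration(paths, v)))
#> 5 3 3        # fastest arrival, in whole days, per current velocity
```

Diet mixing on a synthetic whisker data set drawn from the model's own
likelihood (the wide intervals are the honest output for isotopically
overlapping sources):

```r
iso <- generate_isotopes(seed = 12)
fit_mixing_model(iso$consumers, iso$sources, seed = 13)
#> Isotope mixing model: 5 sources, 2 isotope(s), 20000 draws
#>                    source median  lo95  hi95  rhat
#>          silverfish_group  0.325 0.026 0.720 1.011
#>  borchgrevinki_trematomus  0.191 0.019 0.468 1.013
#>           myctophid_group  0.309 0.077 0.508 1.013
#>        benthic_fish_group  0.088 0.001 0.282 1.020
#>          crustacean_group  0.041 0.002 0.145 1.015
```

`run_pipeline(demo_config())` executes every stage end to end on an
all-synthetic configuration and writes CSV/JSON outputs plus a hashed run
manifest; identical config and seed give byte-identical outputs. A thin
command-line wrapper lives in `inst/scripts/icepulse.R`.

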