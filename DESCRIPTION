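Package: icepulse
Title: Seal Dive Phenology, Sea-Ice Break-Out Timing and Stable-Isotope Diet Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for high-latitude pinniped biologging studies:
    time-depth-recorder signal processing (zero-offset correction, dive detection,
    bottom-phase and wiggle metrics, benthic/pelagic classification), prey-capture
    detection from jaw accelerometry, sea-ice break-out phenology and phytoplankton
    advection travel-time geometry, penalized-smooth seasonal depth phenology with
    individual random effects and AIC covariate comparison, and a Bayesian
    stable-isotope diet mixing model sampled by MCMC. A seeded synthetic-data
    generator emulates every input stream with machine-readable ground truth so the
    full pipeline is testable without field or satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    mgcv,
    lme4,
    signal,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
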