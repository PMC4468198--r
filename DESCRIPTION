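Package: phenorisk
Title: Temperature-Driven Insect Phenology, Pest Risk Indices and Maize
    Yield-Loss Projection Along Altitudinal Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling temperature-dependent insect phenology
    (Logan development rates, exponential-polynomial stage mortality,
    logit/cloglog development-time variability, Stinner and Hilbert-Logan
    adult longevity, gamma-profile fecundity), simulating stochastic
    cohort life tables under fluctuating temperature and extracting
    classical demographic parameters (generation time, net reproduction
    rate, intrinsic and finite rates of increase, doubling time) via the
    Euler-Lotka equation.  From these it computes annual establishment,
    generation and activity risk indices for pests and their parasitoids,
    interpolates them over a digital elevation model with an exact
    thin-plate spline using elevation as a covariate, differences current
    and warmed climate scenarios, and links the activity index to maize
    yield loss per agro-climatic altitude zone through linear regression.
    Includes seeded synthetic-data generators for altitudinal weather
    transects, species parameter profiles, warming scenarios and observed
    losses, so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
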