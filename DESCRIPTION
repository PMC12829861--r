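Package: refugia
Title: Screening Protected Areas as Climate Refugia for Threatened Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to classify protected areas as in situ or ex situ climate
    refugia for rare plant species from gridded habitat-suitability surfaces,
    hectad-scale occupancy records and protected-area polygons. Suitability is
    binarised per species at a percentile of scores over occupied cells, zonal
    maxima are extracted per protected area for current and future periods, and
    each (species, area) pair is classified as occupied-at-risk, in situ
    refugium, ex situ refugium or none. Species-per-area refugia counts are then
    related to area covariates (elevation, elevational range, area, location,
    habitat diversity) with a spatially explicit Bayesian Poisson regression
    using a low-rank Gaussian-process random field fitted by adaptive MCMC. A
    synthetic-landscape generator provides a self-contained study system with
    known structure for testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
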