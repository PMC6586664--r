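Package: carabidedge
Title: Seasonal Spatial Distribution of Carabid Assemblages Across
    Field-Woodlot Ecotones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for seasonal change in the spatial distribution
    of carabid beetles across arable field-woodlot boundaries sampled by
    pitfall-trap transects. Ingests long-format trap catches, pools traps into
    site samples, computes relative abundance and relative species richness
    profiles along the signed boundary gradient, fits Huisman-Olff-Fresco
    (HOF) response curves (types I-V) by deviance minimisation with multistart
    bounded optimisation, compares seasons with stratified bootstrap confidence
    envelopes, and runs constrained ordination from first principles: partial
    canonical correspondence analysis with restricted (block) permutation
    tests, Bray-Curtis principal coordinate analysis, and distance-based
    redundancy analysis for the distance-by-period interaction. Includes a
    negative-binomial community simulator that reproduces the sampling design
    for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
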