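Package: rwlr
Title: Regolith Water Loss Rate Estimation from Dryness-Index Time Series
Version: 0.1.0
Authors@R:
    person("RWLR", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links bedrock geochemistry to vegetation productivity in karst
    landscapes through the Regolith Water Loss Rate (RWLR): the mean
    within-dry-spell slope of the Temperature Vegetation Dryness Index
    (TVDI). Provides the TVDI triangle method (dry/wet edge regression over
    the NDVI/surface-temperature scatter), dry-spell detection in daily
    precipitation records, the RWLR statistic per critical-zone unit,
    all-subsets AIC model ranking with Akaike weights and relative variable
    importance, recursive path models (manifest-variable SEM) with
    chi-square, CFI and RMSEA fit assessment, per-pixel growing-season
    NDVI-temperature correlation with a karst buffer-zone rank-sum
    contrast, and synthetic-data generators (Markov-chain precipitation,
    soil-moisture bucket scenes, structured covariate tables,
    planted-correlation grids) so every stage is testable without satellite
    or station archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
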