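Package: canopyedge
Title: Edge Effects on Canopy Height Change in Fragmented Logged Forest
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landscape analysis of repeat-LiDAR canopy height change in
    fragmented, logged tropical forest during a hot ENSO drought. Provides a
    seeded synthetic-landscape generator (terrain, land cover, repeat canopy
    height surfaces with spatially correlated noise, field-plot censuses and
    microclimate series), terrain metrics (topographic position and wetness
    indices, distance to plantation edge), the repeat-survey gridding and
    pixel-filtering ledger, field-plot canopy statistics (allometry,
    crown-area-weighted height, basal-area dynamics), micrometeorological
    formulas (saturation vapour pressure, vapour pressure deficit, ENSO
    anomalies), and the inference core: an asymptotic edge-effect regression
    fitted by nonlinear least squares or spatial generalized least squares
    with an exponential correlogram, AIC model selection, subset-ensemble
    uncertainty and sample-size-corrected confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    knitr
Config/testthat/edition: 3
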