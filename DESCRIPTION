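Package: firecanopy
Title: Post-Fire Recovery of Canopy 3D Structure from Canopy Height Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the recovery of woodland canopy structure
    after stand-replacing wildfire from airborne-laser-scanning canopy height
    models (CHMs). Computes four plot-level structural metrics (maximum canopy
    height as an upper height percentile, canopy cover above a height
    threshold, the coefficient of variation of canopy height, and a normalized
    rumple index from surface triangulation), fits additive smooth recovery
    trajectories of each metric over a stand-age chronosequence with rainfall
    and plot-size effects, derives decadal rates of change, trajectory extrema
    and rainfall contrasts, and inverts the structure-age relationship to
    predict stand age with a stratified repeated hold-out validation. A
    two-tier synthetic chronosequence generator (plot-level metric tables and
    explicit tree-level stand scenes rasterized to 1 m CHMs) makes the whole
    pipeline testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
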