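Package: blueCinorg
Title: Inorganic Carbon Burial Accounting for Blue Carbon Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying calcium-carbonate (inorganic carbon)
    burial in vegetated coastal ("Blue Carbon") sediments. Implements
    lead-210 chronologies under the constant flux-constant sedimentation
    model, conversion of CaCO3 content and sediment accretion rates into
    inorganic-carbon burial rates, location-level aggregation and global
    upscaling with tropical partitioning, CO2-offset and carbonate
    mass-balance budgets (net calcification, emission, allochthonous
    fraction), Hedges' g random-effects meta-analysis of vegetated versus
    unvegetated carbonate content, and a synthetic sediment-core generator
    with a parameter-recovery harness so every pipeline stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite
Config/testthat/edition: 3
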