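Package: droughtrec
Title: Ecosystem Recovery Time from Compound Hot-Dry and Dry Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects plain dry spells and compound hot-dry events from monthly
    climate and vegetation series, estimates ecosystem recovery time after the
    month of maximum vegetation loss, and contrasts the two event types
    (delta-RT). Includes a 3-month Standardized Precipitation Index (SPI-3)
    implementation with per-calendar-month gamma fitting, a deseasonalizing and
    detrending anomaly operator, random-forest attribution of delta-RT to
    climatic and severity factors with partial-dependence curves, and inversion
    of canopy conductance and light-saturated assimilation from flux-tower-style
    records. A synthetic-data generator with planted ground truth (event timing,
    depth and true recovery time) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    randomForest,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
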