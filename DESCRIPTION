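Package: panelgt
Title: Generalizability Theory for Crowdsourced Rating Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quality control and reliability analysis of rating
    panels that score physician communication skills (or any rated
    performance) on ordinal scales. Implements rater quality-control
    screens (incomplete raters, straight-lining, leave-one-out
    reliability outliers), item-to-vignette score aggregation,
    generalizability-study (G-study) variance-component estimation by
    expected mean squares for fully crossed person x vignette x rater
    designs and by analogous-ANOVA (Henderson Method 1) for unbalanced
    rater-nested-within-person designs, decision-study (D-study)
    projection of generalizability and dependability coefficients over
    grids of panel sizes, rater-group stringency and agreement
    comparison, and a synthetic-panel generator with known
    variance-component ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
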