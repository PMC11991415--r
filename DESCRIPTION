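Package: chlorocal
Title: Chlorophyll Calibration for Low-Cost Multispectral Leaf Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Calibration pipeline relating multispectral leaf reflectance from
    low-cost 6- and 18-channel sensors to per-area chlorophyll content.
    Provides white-reference normalization, DMF-extraction reference
    chlorophyll computation, replicate-residue Mahalanobis outlier screening,
    single-response partial least squares regression with AIC-driven
    latent-variable selection inside a double-nested, group-stratified
    Monte-Carlo cross-validation, learning curves, and per-chip channel-subset
    analysis for multi-chip sensors. A synthetic-data module simulates leaf
    populations with chlorophyll-dependent reflectance so the whole pipeline
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
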