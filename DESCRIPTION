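Package: fluxtraits
Title: Closed-Chamber CO2 Flux Estimation and Plant Trait Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Processing and quality control for field campaigns that pair
    closed-chamber ecosystem CO2 flux measurements with plant functional
    trait sampling in boreal and alpine grasslands. Fits an exponential
    concentration model to 1 Hz chamber closures and converts the initial
    slope into an areal flux, partitions fluxes into net ecosystem exchange,
    ecosystem respiration and gross primary production with a flag-based
    quality-control decision tree and a diurnal GPP baseline correction,
    derives leaf functional traits (specific leaf area, leaf dry matter
    content, elemental ratios) with threshold-based validation, screens
    assimilation-temperature response curves by spline multimodality and a
    Sharpe-Schoolfield optimal-temperature criterion, and applies range
    filters to microclimate logger series. A synthetic-data module generates
    every input with known ground truth so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    minpack.lm,
    purrr,
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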