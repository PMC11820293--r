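Package: thermofill
Title: Canopy-Temperature Phenotyping and Logistic Grain-Filling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for thermal-infrared phenotyping of
    field-grown wheat: per-plot canopy temperature (CT) extraction from
    single-band temperature rasters, neighbour-based CT normalization to
    remove shared ambient effects, multi-season classification of lines
    into cold-, warm- and mediate-temperature types, logistic modelling of
    thousand-grain-weight accumulation with derived grain-filling
    parameters (initial weight, maximum and mean filling rates, active
    filling period, filling end time), and trait-CT correlation and group
    contrast reporting.  A synthetic-data generator with known ground
    truth drives recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
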