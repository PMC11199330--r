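Package: fjordpp
Title: In Situ Primary Production Analysis for Glacier-Influenced Arctic Fjords
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the complete in-situ primary-production workflow used
    in Arctic fjord field campaigns: conversion of carbon-14 light/dark
    bottle activities to volumetric carbon fixation rates Pe(z), with total
    inorganic carbon derived from in-situ temperature, salinity and pH;
    spectrophotometric chlorophyll-a from ethanol extracts; temperature-
    salinity water-mass classification; trapezoidal depth integration of
    production profiles to daily areal rates Pi; and zone-wise statistical
    comparison (normality and variance-homogeneity gated ANOVA versus
    Kruskal-Wallis). A synthetic-cast generator emulates glacier-to-outer
    zone stratification, turbidity-controlled light attenuation and
    subsurface chlorophyll maxima, providing ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    car,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
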