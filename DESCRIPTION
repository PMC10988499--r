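Package: capdomain
Title: Capillary Domain Analysis and Tissue Oxygenation Modelling for
    Skeletal Muscle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies skeletal-muscle capillary supply from capillary
    coordinate maps: capillary-domain (Voronoi trapping-region)
    tessellation, global and local supply indices (capillary-to-fibre
    ratio, capillary density, fibre cross-sectional area, capillary
    domain area and its log-SD heterogeneity), a steady-state oxygen
    diffusion-consumption model with Michaelis-Menten kinetics solved
    per trapping region to predict tissue PO2 and hypoxic fraction,
    fatigue-index and functional-hyperaemia metrics from tension and
    blood-flow traces, and univariate group statistics (one-way ANOVA
    with Tukey HSD, fold-change/t-test/FDR volcano tables, and a
    compound-identification matching filter). Includes synthetic-data
    generators emulating oxidative-core and glycolytic-cortex muscle
    phenotypes, twitch-train tension traces, hyperaemia flow traces and
    log-normal metabolite matrices with planted effects.
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
    Matrix,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
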