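Package: calcitox
Title: Single-Cell Calcium-Imaging Responder Calling and Benchmark-Concentration
    Neurite-Specificity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for functional neurotoxicity screening on sensory neuron
    cultures. Implements per-cell responder calling from Fluo-4 calcium-imaging
    traces using a noise-derived per-well threshold (mean + 3 SD of the
    negative-control delta-F, capped), resting-baseline calcium quantification,
    attenuation profiling of agonist responses as percent of untreated control,
    and a two-endpoint benchmark-concentration (BMC25) prediction model that
    classifies compound effects as neurite-specific or cytotoxic from neurite
    area and viability concentration-response curves. Includes a seeded
    synthetic-data generator for single-cell fluorescence traces and
    concentration-response tables so the whole pipeline is testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
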