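Package: zahnreihen
Title: Tooth Replacement Waves, Odontochronology and Replacement-Pattern
    Evolution in Fossil Dentitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative analysis of tooth replacement in fossil reptile
    dentitions. Computes Fastnacht-style replacement indices from per-tooth
    measurements, segments each dentition into replacement waves (Zahnreihen),
    measures the spacing between successive waves (Z-spacing) and classifies
    the replacement-wave direction. Estimates tooth formation time and daily
    dentine apposition rate from von Ebner incremental-line width series and
    infers tooth replacement rates for newly erupted teeth or from
    successive-generation increment counts. Time-calibrates phylogenies from
    taxon first-appearance dates with the 'equal' branch-sharing method and
    reconstructs ancestral tooth-replacement patterns by maximum-likelihood
    Mk-model fitting, Akaike-weight model averaging and stochastic character
    mapping. Ships ground-truthed simulators for dentitions, increment series
    and discrete characters so every stage can be validated without fossil
    material.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
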