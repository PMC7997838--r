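Package: aromkin
Title: Kinetic Modeling of Anaerobic Co-Metabolism of Plant-Derived Aromatic Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for kinetic modeling of the anaerobic co-metabolism of
    lignin-derived aromatic monomers (p-hydroxyphenyl, guaiacyl and syringyl
    types) by photoheterotrophic bacteria in batch culture. Provides a
    pathway-network data model with first-order and inhibition rate laws
    (competitive inhibition by a secondary substrate and substrate
    self-inhibition), fixed-step Euler integration of the network ODEs with
    Gompertz biomass forcing, parameter estimation by residual-sum-of-squares
    minimization with multi-start Nelder-Mead, a ladder of nested
    pathway-structure hypotheses for model comparison, and a synthetic
    batch-reactor data generator with known ground truth for testing
    identifiability and case discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
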