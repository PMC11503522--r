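Package: lipidnms
Title: Native Mass Spectrometry Analysis of Membrane Protein-Lipid Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying lipid binding to intact membrane protein
    complexes observed by native nano-electrospray mass spectrometry.
    Provides a sequential lipid-binding equilibrium model with forward
    species-distribution prediction and multi-start estimation of per-site
    dissociation constants from titration mole fractions; charge-state
    deconvolution of m/z spectra into zero-charge mass spectra with
    lipid-stoichiometry assignment, mole fractions and weighted average
    charge states; a nanoESI spectrum and titration simulator with
    configurable charge-state distributions, peak shapes and ion-counting
    noise; sensitized-emission FRET correction for plate-based lipid
    binding assays; and a config-driven pipeline with plain-text spectrum
    and CSV titration input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
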