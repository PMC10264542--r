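Package: azperm
Title: Membrane Permeation of Azide/Hydrazoic Acid from pH-Dependent
    Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models passive membrane permeation of the azide ion /
    hydrazoic acid pair (N3- / HN3) from octanol/water partition
    measurements. Fits a two-species (neutral/anionic) distribution
    model Q(pH), derives transfer and protonation free energies and
    compartment concentration ratios, computes effective permeability
    and mass retention from parallel artificial membrane permeability
    assay (PAMPA) well concentrations, builds one-dimensional
    free-energy profiles across a membrane separating compartments at
    different pH, and solves the Smoluchowski drift-diffusion equation
    on those profiles by finite differences to predict membrane
    permeability and permeation rate constants, cross-checked against
    the inhomogeneous solubility-diffusion closed form. Includes
    synthetic-data generators with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
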