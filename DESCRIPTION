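Package: dimerfold
Title: Equilibrium Folding Analysis of Homodimeric Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-state thermodynamic linkage models for denaturant-induced
    equilibrium unfolding of homodimeric proteins such as effector
    procaspases.  Implements linear-extrapolation free energies and
    closed-form mass-balance solvers for single-chain dimer mechanisms,
    species-population landscapes as a function of urea and protein
    concentration, average-emission-wavelength reduction of fluorescence
    scans, global multi-probe fitting with linked thermodynamic parameters
    and local spectroscopic baselines, pH-titration (pKa) analysis, and a
    synthetic-data generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
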