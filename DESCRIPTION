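Package: qspHER2
Title: Quantitative Systems Pharmacology Modeling of HER2-Positive Breast
    Cancer Therapeutics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic quantitative systems pharmacology (QSP) model of
    ErbB-driven (HER2-positive) breast cancer. Couples an ordinary
    differential equation network of ErbB receptor signaling (receptor-ligand
    binding, dimerization, transphosphorylation, FOXO-mediated HER3 feedback,
    PI3K/AKT and Raf/ERK cascades) to the pharmacology of five therapeutics
    (lapatinib, pyrotinib, T-DM1, T-DXd, capecitabine), mouse compartmental
    pharmacokinetics, and tumor growth/death dynamics. Provides simulated
    signaling, viability and xenograft protocols, Bliss-independence synergy
    surfaces, PRCC and Sobol global sensitivity analysis, pattern-search
    parameter calibration with bootstrap uncertainty, resistance-phenotype
    presets, and a synthetic calibration-data generator with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    lhs,
    xml2
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
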