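Package: vesiclebias
Title: Quantification of Ligand and Mutation-Induced Signaling Bias from
    Single-Vesicle Dose-Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify ligand- and mutation-induced bias in receptor
    phosphorylation from single-vesicle fluorescence ratio measurements.
    Implements fixed-slope Hill fitting with correction for constitutive
    (ligand-independent) phosphorylation, relative bias coefficients for
    ligand and mutant comparisons, transducer-function fitting in the
    operational-model framework (K_resp, R_max, phosphorylation efficiency),
    absolute bias coefficients on a detection-gain-free scale, Monte-Carlo
    propagation of parameter uncertainty, and the associated hypothesis
    tests (one-way ANOVA with Tukey HSD, pairwise t-tests with Holm-Sidak
    adjustment). A synthetic single-vesicle data generator reproduces the
    statistical structure the analysis assumes, so the full pipeline is
    testable without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
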