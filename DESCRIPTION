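Package: epimap
Title: Epistasis Between Beneficial Mutations via a Phenotype-to-Fitness Map
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of epistasis between beneficial mutations from
    single- and double-mutant fitness assays. Computes deviation-from-additivity
    statistics with Welch/Bonferroni significance batteries, fits a unimodal
    gamma-shaped phenotype-to-fitness map with additive latent phenotypes by
    iterative imputation and nonlinear least squares, performs
    leave-one-double-out prediction, and compares the fitted map against a
    two-dimensional Fisher-geometric model with a Gaussian fitness function by
    simulation-based histogram likelihoods and AIC. Includes a seeded synthetic
    replicate-assay generator and a pipeline command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
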