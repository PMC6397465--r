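Package: acetylflux
Title: Constraint-Based Modeling of Metabolism-Driven Protein Acetylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scale metabolic modeling of the link between cellular
    metabolism and protein/histone acetylation. Augments a metabolic network
    with a nuclear acetylation reaction fed by nuclear ATP-citrate lyase,
    predicts acetylation flux under nutrient perturbations and gene deletions
    using flux balance analysis with a weighted secondary objective, infers
    transcriptome-constrained acetylation states with linear iMAT- and
    GIMME-style programs, and stratifies sensitivity to lysine-deacetylase
    (KDAC) inhibitors by predicted acetylation flux. Ships a deterministic
    core-carbon toy network in which acetylation behaves as overflow
    metabolism, plus seeded generators for expression cohorts and
    drug-response tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    xml2
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
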