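Package: mrmediate
Title: Two-Sample Mendelian Randomisation with Mediation Decomposition
    and Pathway Enrichment
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation from GWAS summary
    statistics: instrument selection with greedy LD clumping and strength
    diagnostics, univariable causal-effect estimation (random-effects
    inverse-variance weighting, weighted median, MR-Egger, MR-PRESSO),
    multivariable-MR mediation decomposition with propagation-of-error
    intervals, cis-eQTL based pathway over-representation analysis with
    Benjamini-Hochberg FDR control and drug/ATC annotation, and a seeded
    synthetic summary-statistics generator with known causal, mediation and
    pleiotropy structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
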