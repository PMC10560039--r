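Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening, Sensitivity Analysis and
    Mediation from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A config-driven two-sample Mendelian randomization (MR) toolkit for
    screening many exposures against an outcome across a discovery and a
    replication cohort. Implements instrument selection by p-value thresholding
    and greedy LD clumping, allele harmonization with palindromic-variant
    policies, five causal estimators (Wald ratio, inverse-variance weighted,
    MR-Egger, weighted median, simple and weighted mode) plus multivariable
    IVW, a sensitivity suite (Cochran's Q, Egger intercept test, MR-PRESSO
    global, outlier and distortion tests, leave-one-out, scatter and funnel
    plot data), fixed-effect meta-analysis across cohorts, and two-step
    mediation MR with mediation proportions. A synthetic GWAS
    summary-statistics generator with known ground truth (instrument effects,
    LD blocks, balanced or directional pleiotropy, mediator chains, two
    cohorts) makes every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
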