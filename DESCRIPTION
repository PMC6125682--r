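Package: coreis
Title: Discovery and Validation of an Insulin-Sensitivity Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering fasting insulin-sensitivity
    (IS) related genes from multi-cohort expression-array data and validating
    them against clinical interventions. Implements tissue-adaptive probe
    filtering and probe-set assembly (a custom chip definition), quantile
    normalization with median-polish summarization and NUSE array quality
    control, HOMA-based insulin-sensitivity phenotyping, per-cohort
    covariate-adjusted sequential-ANOVA association with Stouffer p-value
    meta-analysis, FDR and cross-cohort directional filtering (the CORE-IS
    gene list), and an intervention layer correlating per-subject expression
    changes with per-subject IS changes (the Delta-IS selection) with a
    cumulative-binomial consistency statistic. Ships a synthetic-data
    generator with planted truth so every stage is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
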