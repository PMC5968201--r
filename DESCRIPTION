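Package: combiscreen
Title: Analysis of miRNA/Drug Combination Viability Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for plate-based miRNA and drug combination
    viability screens in cancer cell lines. Provides ratio-to-global-median
    normalization with median-absolute-deviation (MAD) hit calling for
    single-agent miRNA screens, four-parameter logistic dose-response fitting
    with IC50 estimation and a working-concentration cap, exact Mann-Whitney
    rank-sum conjunction tests with per-experiment Bonferroni control for
    calling true miRNA/drug interactions, and a downstream expression
    association stage (variation filtering, Spearman correlation screening,
    lentiviral concordance filtering, gene-list intersection). Seeded
    synthetic-data generators reproduce the statistical structure of every
    stage so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
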