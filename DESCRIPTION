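Package: itlsig
Title: Cell-State Mapping and Immunosuppressive Treg-Like Signature Analysis
    for Glioblastoma Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting the TGFBR2-driven immunosuppressive Treg-like
    (ITL) transcriptional state in mesenchymal glioma stem cells. Provides
    single-cell quality control and log normalization, per-cell gene-module
    scoring with expression-matched control genes, the two-axis glioblastoma
    cellular-state (MES/AC/OPC/NPC) coordinate mapping, single-sample and
    preranked gene-set enrichment with permutation-based normalized
    enrichment scores, a differential-expression intersection pipeline for
    signature derivation, correlation panels with multiple-testing
    correction, and group-comparison statistics. A negative-binomial
    synthetic-data generator with known ground truth makes every stage
    testable without external cohort downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
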