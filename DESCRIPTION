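Package: jdr
Title: Joint Dimension Reduction for Translating Model-System Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Horizontal integration of two gene-expression cohorts that share a
    gene axis using angle-based joint and individual variation explained
    (AJIVE). Each cohort is decomposed into joint, individual, and residual
    matrices via a two-stage truncated singular value decomposition with
    principal-angle analysis. The package quantifies per-sample and per-gene
    joint behaviour (a signed log variance-ratio statistic with permutation
    p-values and SAM-style FDR cutoffs), selects initial signal ranks by a
    half-split bootstrap, simulates paired blocks with planted joint and
    individual structure for validation, and trains elastic-net drug-response
    models on the decomposed matrices to improve out-of-sample clinical
    prediction from cell-line and mouse-model data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
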