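Package: foxnet
Title: Network-Centric Transcriptomic Screening for FOXM1-Pathway Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A connectivity-map style screening pipeline for finding small
    molecules that phenocopy knockdown of a network proxy gene (NPM1 standing
    in for FOXM1) in LINCS-like z-score signature panels, together with its
    downstream computational validation: consensus aggregation of replicate
    signatures, guilt-by-association screening features across cell lines,
    target-panel consensus tables, codirectional differential-expression
    signatures with Benjamini-Hochberg correction, preranked gene-set
    enrichment with permutation-based normalized scores and FDR, thresholded
    Manders colocalization coefficients with exact Mann-Whitney group
    comparison, Pfaffl relative quantification for RT-qPCR, and synthetic-data
    generators with stored ground truth for recovery testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmnet,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
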