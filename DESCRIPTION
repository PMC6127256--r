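Package: seesawtf
Title: Predicting Cell-Fate Determinant Transcription-Factor Pairs from
    Transcriptomics and Prior-Knowledge Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate cell-fate determinant transcription-factor
    (TF) pairs for binary cell differentiation events from gene expression of
    a progenitor and its two daughter cell types together with a
    prior-knowledge network (PKN) of directed, signed TF-TF interactions.
    Implements the normalized ratio difference (NRD) statistic under the
    seesaw model of differentiation, differential-expression and NRD-based
    candidate filtering, Boolean-consistency pruning of the PKN with
    multi-solution sampling, scoring of TF pairs by strongly connected
    component (SCC) co-membership, reciprocal rank fusion of rankings from
    multiple predictors, and a PKN-perturbation sensitivity analysis.
    Includes a fully seeded synthetic-data generator that plants seesaw
    motifs so every stage of the pipeline can be exercised without external
    data.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
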