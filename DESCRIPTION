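Package: atacdyn
Title: Temporal Enhancer Dynamics from ATAC-Seq Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies putative enhancers by their chromatin-accessibility
    dynamics across a staged differentiation time course (fuzzy c-means
    clustering of negative-binomial GLM-flagged dynamic ATAC-seq peaks into
    named temporal groups), links enhancers to genes by the single nearest
    transcription start site within a distance window, scores enhancer
    classes against differential-expression gene sets and tissue H3K27ac
    enhancer sets with a log2 observed/expected statistic and chi-squared
    significance, and aligns single-cell RNA-seq clusters between datasets
    by bootstrap resampling of per-cluster mean expression. Ships a
    synthetic-data generator with planted ground truth so the full pipeline
    is exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    e1071,
    knitr,
    MASS,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
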