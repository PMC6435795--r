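Package: ecrank
Title: Exponential Consensus Ranking for Docking-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining per-molecule results from multiple molecular
    docking programs into a single hit list. Implements Exponential Consensus
    Ranking (ECR), which scores each molecule by a sum of exponential kernels
    of its per-program ranks, together with five baseline consensus strategies
    (rank-by-rank, rank-by-vote, rank-by-number, average of auto-scaled
    scores, Z-score) and a random scoring function control. Includes the
    merging-and-shrinking procedure for receptor ensembles, virtual-screening
    evaluation metrics (enrichment factors, enrichment plots, ROC curves and
    AUC), a tie-shuffling protocol for uncertainty estimates, a best-strategy
    success-counting summary, and a synthetic multi-program screen generator
    so the whole pipeline is testable without docking software.
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
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
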