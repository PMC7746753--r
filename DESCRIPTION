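Package: matrixgc
Title: Promoter Binding-Site Prediction by Combined PWM and GC-Content Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies gene promoters as bound or not bound by a GC-preferring
    DNA binder (such as MeCP2) using a position weight matrix scan combined
    with a flanking GC-content filter, and provides the validation apparatus
    around the classifier: ROC calibration of the score threshold against
    ranked positive and bootstrapped negative control gene sets, Fisher exact
    tissue-expression contrasts, a Monte Carlo permutation test of
    differential-expression enrichment in candidate gene sets, a degree-based
    permutation null for protein-protein interaction network connectivity with
    hub calling, and deterministic synthetic-data generators for every input
    class so the whole toolkit is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
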