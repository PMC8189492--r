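Package: padjustr
Title: Tidy Multiple Hypothesis Testing Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-frame-first implementations of the classical multiple
    hypothesis testing corrections: Bonferroni, Sidak, Holm (step-down),
    Hochberg (step-up, plus a non-standard rank-multiplier variant),
    Benjamini-Hochberg and Benjamini-Yekutieli false discovery rate control,
    Storey's positive FDR with pi0 estimation, the proportion of false
    positives (PFP), and q-values. Ships a synthetic p-value generator with
    ground-truth labels and a Monte-Carlo replicate engine that measures each
    method's empirical family-wise error rate, false discovery rate and power,
    a decision-tree method recommender, CSV/TSV table input and output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
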