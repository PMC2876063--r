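Package: mirdirect
Title: Direct MicroRNA Target Identification from Matched Tumor-Normal Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-step screen for calling direct mRNA targets of microRNA
    dysregulated between patient-matched tumor and normal samples. Differential
    expression of both modalities is assessed with a signal-to-noise statistic
    and permutation p-values (exact enumeration or Monte Carlo), with
    Benjamini-Hochberg and Storey q-value multiple-testing control. Candidate
    regulator-target pairs are restricted to genes carrying an exact,
    multi-species-conserved seed-complement site in their 3'UTR (scanned de
    novo from sequence or imported from a TargetScan-style annotation), then
    screened by a strict per-class Pearson anti-correlation cutoff with
    permutation significance. Also provides comparative-Ct qPCR normalization
    with data-driven housekeeping selection, a weighted-voting classifier with
    leave-one-out cross-validation, and a seeded synthetic-data generator that
    plants differential features, anti-correlated regulator-target edges, and
    conserved seed sites for end-to-end validation.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
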