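Package: regensig
Title: Cross-Species Regeneration Signature Meta-Analysis by Rank Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis of two-group regeneration experiments measured on
    different platforms and species. Per-experiment log2 fold changes are
    computed on a common orthologous gene universe, probes are collapsed to
    genes, genes are rank-ordered within each experiment, ranks are averaged
    across experiments, and top-N signature lists are extracted. Signature
    lists are intersected (Venn regions with a seeded permutation null for the
    central overlap) and tested for term enrichment with one-sided Fisher's
    exact tests under Benjamini-Hochberg and Bonferroni adjustment. A
    synthetic-study generator plants a shared signature across simulated
    multi-platform, two-species experiments so the whole pipeline is
    verifiable at desk scale.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
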