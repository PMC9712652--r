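Package: tinburden
Title: Rare-Variant and Structural-Variant Burden Analysis for
    Extreme-Phenotype Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Collapsing gene-burden analysis of rare coding variants against
    external population reference panels, with replication across cohorts, a
    structural-variant prioritization stage (size window, blacklist-artifact
    removal, known-variant concordance, simplified ACMG-style classification,
    constrained-region overlap, ultra-rare flagging, carrier-frequency burden),
    clinical subgroup comparisons for extreme-phenotype designs, and a
    probe-level co-expression check. Includes a synthetic-cohort simulator with
    known ground truth (planted per-gene odds ratios, recurrent deletions) so
    every stage is testable end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    vcfR,
    IRanges,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
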