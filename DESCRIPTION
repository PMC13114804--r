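Package: mircons
Title: Cross-Cohort Consensus Gene Signatures and miRNA Target
    Over-Representation for Disease Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving direction-aware consensus gene signatures
    from per-cohort differential-expression summary tables ("top-tables"),
    partitioning them into disease-specific, shared-concordant and
    shared-discordant sets, testing validated miRNA target regulons for
    over-representation with hypergeometric statistics and
    Benjamini-Hochberg correction, prioritizing candidate miRNAs with a
    composite score, and ranking hubs in bipartite miRNA-mRNA networks.
    Includes a seeded synthetic-data generator with planted gene programs
    and hub regulons so the whole pipeline is testable without external
    downloads, plus a single-call pipeline orchestrator with a
    deterministic run manifest.
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
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
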