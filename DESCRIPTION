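Package: drugrepo
Title: Evidence-Weighted Knowledge Graphs for Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds heterogeneous drug-protein-gene-disease knowledge graphs
    from tabular interaction assertions with nanopublication-style provenance,
    assigns each assertion a probability from its evidence (curated source or
    rated experimental detection method), merges redundant records per triple
    by composite Z-score (Stouffer) voting, and proposes drug-repositioning
    candidates by joint-probability path expansion from a disease of interest.
    Includes hit-based precision/recall/f-measure evaluation with threshold
    sweeps, Scott's Pi inter-annotator agreement, and deterministic synthetic
    fixture generators for end-to-end testing.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
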