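Package: cernet
Title: Competing Endogenous RNA Network Assembly from RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated, file-driven pipeline for circRNA-centred competing
    endogenous RNA (ceRNA) analysis from bulk RNA-seq counts: TMM
    normalization and a negative-binomial exact test for differential
    expression with Benjamini-Hochberg control, hypergeometric/EASE gene-set
    over-representation, score-filtered protein-protein interaction graphs
    with degree/betweenness/closeness core-protein ranking, multi-database
    miRNA-target consensus, and tripartite circRNA-miRNA-mRNA network
    assembly with degree-based hub-gene selection. A synthetic-data module
    generates every pipeline input with planted ground truth so each stage is
    testable without external database access.
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
    utils
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
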