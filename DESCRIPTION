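Package: woodnet
Title: Gene Regulatory Network Inference for Wood Development from
    Co-Expression and Promoter Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers cell-wall gene regulatory networks in woody stems from
    tissue-fraction RNA-seq profiles and promoter motif content. Provides
    tight consensus co-expression clustering with unclustered genes,
    signed weighted-correlation networks with topological overlap and
    module eigengenes, strand-aware promoter extraction and position
    weight matrix scanning with exact p-values, motif and Gene Ontology
    enrichment, motif-plus-correlation network construction with a
    nested-regression screen for regulators without known motifs,
    cross-species conservation scoring through orthogroups, and
    Ks-spectrum dating of whole-genome-multiplication duplicates. A
    synthetic-data generator with full ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
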