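Package: meshpool
Title: Subtree-Pooled Gene-Set Enrichment for Hierarchical Disease
    Taxonomies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Links query gene sets to nodes of a hierarchical disease
    taxonomy (a MeSH-style forest of disease trees) by pooling
    gene-disease associations across disease subtrees, with significance
    assessed by permutation of gene labels so that the correlation
    structure between related diseases is preserved.  Includes a
    closed-form hypergeometric companion, a withheld-link
    cross-validation experiment comparing pooled against direct-node
    enrichment, a density-of-significant-enrichment summary over
    top-level disease categories, and a synthetic-data generator that
    emulates annotation-precision jitter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
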