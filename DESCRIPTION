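Package: srnakit
Title: Small RNA Annotation Toolkit: Hairpin Calling, Repeat Association
    and Palindrome Motif Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for annotating small RNA sequencing
    pools (miRNA, piRNA and crasiRNA size classes). Provides adapter clipping
    and size-class selection, exhaustive ungapped all-hits read mapping with a
    bounded mismatch count, maximum-base-pair hairpin folding with stem-loop
    validation for miRNA gene calling, reference hairpin/mature comparison,
    gene-model expansion and miRNA target calling, repeat association of
    piRNA/crasiRNA pools, read-peak clustering with ChIP-enrichment overlap,
    and a discontiguous-palindrome (mirror) motif score with a
    composition-preserving permutation p-value. Ships a deterministic
    synthetic-data generator with a machine-readable truth ledger used for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    stringi,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
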