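Package: aicescan
Title: Mining Actinobacterial Genomes for Integrative and Conjugative Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Detects integrative and conjugative elements (ICEs) in
    high-G+C actinobacterial genomes, in particular actinomycete ICEs
    (AICEs) that conjugate through a single FtsK/SpoIIIE-type DNA
    translocase, and T4SS-type ICEs. Provides position-specific protein
    profile construction and search for the integration, replication and
    transfer modules; co-localization rules that call elements, remnants
    and plasmid-borne excised forms; direct-repeat attachment-site
    resolution anchored at tRNA 3' ends with in-silico excision of
    circular forms (including multi-attL and tandem arrangements);
    subfamily extraction from bootstrapped phylogenies; per-niche and
    per-suborder distribution summaries; and a synthetic-genome simulator
    with planted elements and decoys for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
Imports:
    ape,
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp
SystemRequirements: C++17
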