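Package: poolscreen
Title: Pooled CRISPR/Cas9 Screen Analysis from Raw Reads to Gene Rankings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained workflow for pooled CRISPR/Cas9 knockout
    screens: adapter location and trimming of (optionally staggered)
    amplicon reads, local alignment of extracted 20 nt sgRNA candidates
    against the screen library with unique/tolerated/ambiguous/failed
    classification, read counting with a cpm count cutoff and cpm, total
    or size-factor normalization, per-sample count-distribution
    diagnostics including the Gini coefficient, negative-binomial
    enrichment and depletion tests with Benjamini-Hochberg correction,
    adjusted robust rank aggregation (alpha-RRA) gene rankings with
    permutation p-values, and hierarchical sample clustering. A
    synthetic-screen simulator generates libraries, negative-binomial
    counts with spiked effects, and staggered FASTQ reads so the whole
    pipeline is testable without external data or aligner binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
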