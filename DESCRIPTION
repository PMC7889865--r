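Package: diploidlr
Title: Reference-Assisted Diploid Assembly and Variant Discovery from Linked Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs long DNA molecules from barcoded linked-read
    alignments, phases heterozygous SNPs into haplotype blocks with a
    Bayesian parity model and recursive molecule clustering, partitions the
    genome at high-confidence cut points, performs per-haplotype local
    assembly with a built-in de Bruijn backend, stitches minicontigs into
    diploid contigs, and calls SNPs, small indels and structural variants
    with zygosity and phase from contig-to-reference alignments. Includes
    post-analysis of structural variants (cross-callset merging, Alu and
    tandem-repeat classification, ancestral-allele inference from outgroup
    flank alignments, derived-allele segregation patterns) and a synthetic
    diploid linked-read simulator with full truth tracking so every stage
    is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
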