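Package: otvar
Title: Variant-Aware Off-Target Detection and Scoring for CRISPR-Cas9
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and scores CRISPR-Cas9 off-target sites while taking an
    individual's sequence variants into account. Builds a personalised
    "variant genome" from a VCF (variant-bearing subsequences with 22 bp
    flanks, expanded per haplotype or per variant combination), searches
    reference and variant sequences for protospacer matches with up to
    8 mismatches and configurable PAM motifs using a pigeonhole
    seed-and-extend strategy verified against a brute-force oracle, and
    scores candidate sites with the MIT position-weight score, a CFD-style
    penalty-table score, and a Random-Forest activity model whose full
    curation, mismatch-weighted downsampling, training and backward
    feature-selection pipeline is included. A simulator generates synthetic
    genomes, variants, guides, planted off-target sites and labelled
    training tables so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    generics,
    ggplot2,
    jsonlite,
    randomForest,
    pROC,
    vcfR,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
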