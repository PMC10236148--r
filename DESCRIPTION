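Package: ncmapr
Title: Proteogenomic Annotation of Noncanonical MHC Class I Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for placing de novo sequenced MHC class I peptides back
    onto the genome. Builds a three-frame translation of unspliced pre-mRNA
    from protein-coding genes as a noncanonical search space, classifies
    peptides as canonical, noncanonical or unmapped under an
    isobaric-aware mismatch rule, recovers genomic coordinates of
    noncanonical peptides in BED form, annotates them by gene feature
    (5'UTR, intron, 3'UTR, alternative exonic frame), tests mechanistic
    explanations (upstream near-cognate start codons, intron retention
    reading frames, frameshift-indel mutant proteomes), compares peptide
    sets between cohorts by genomic overlap, triages cancer-selective
    candidates through expression and protein-evidence filters, and
    calibrates de novo confidence-score thresholds to a target accuracy.
    Ships a deterministic synthetic-fixture generator so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    digest,
    dplyr,
    generics,
    ggplot2,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
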