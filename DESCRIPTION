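Package: sistercomp
Title: Comparative Genomics of Recently Diverged Bacterial Sister Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise comparative-genomics pipeline for near-identical
    ("sister") bacterial genomes: anchor-based collinear whole-genome
    alignment and SNP extraction, codon-aware synonymous/non-synonymous
    classification and regional substitution summaries, GC-skew profiling
    with replication-origin prediction and inversion-scenario ranking,
    maximal direct/inverted repeat discovery and insertion-sequence
    copy-number analysis, reciprocal-best-hit orthology, and a gene
    neighborhood census of transcriptional-regulator protein domains
    around reductive-dehalogenase (rdhA-like) anchor genes. Includes a
    synthetic sister-genome simulator that plants mutations with a
    recorded truth table so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
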