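Package: cohortref
Title: Cohort-Specific Reference Genomes for Metagenome Compression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs lightweight, cohort-specific reference genomes for
    reference-based compression of shotgun metagenomic sequencing data.
    Normalizes a basic microbial reference catalog (gap removal, segment
    concatenation), filters read alignments by mapping quality,
    perfect-match CIGAR and mismatch budget with best-alignment selection,
    ranks genomes by mapping rate, emits a top-N multi-FASTA reference, and
    quantifies the compression gain with a minimal lossless reference-based
    codec. Includes a built-in ungapped aligner and a synthetic community
    simulator so the full pipeline runs end-to-end on generated data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    BiocGenerics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
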