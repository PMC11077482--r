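Package: proteorefine
Title: Proteogenomic Validation and Refinement of Genome Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for validating and refining genome annotation with
    peptide-level mass-spectrometry evidence. Predicts open reading frames
    in assembled transcript contigs, digests protein databases in silico,
    isolates peptides exclusive to the transcript-derived database, aligns
    parent contigs to the genome with a splice-aware anchor-chain aligner,
    classifies peptide-supported contigs as refined gene structures,
    putative novel genes, or unaligned homology-supported candidates,
    detects single-amino-acid-variant candidates from near-perfect
    alignments, and projects peptides to genomic coordinates for BED12
    genome-browser tracks. Includes a seeded synthetic-data generator with
    a truth manifest for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
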