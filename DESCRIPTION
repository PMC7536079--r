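Package: vntrfam
Title: Tandem-Repeat Architecture Analysis of Multigene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the sequence architecture of multigene
    families whose coding regions carry in-frame variable-number tandem
    repeats (VNTRs), modelled on invertebrate C-type lectin families.
    Decomposes coding sequences into ordered arrays of 30/33-nt repeat
    units, assigns members to types by a diagnostic six-amino-acid motif,
    builds neighbour-joining phylogenies with bootstrap support over
    repeat-masked protein alignments, catalogues repeat arrangement
    patterns, infers slipped-strand-mispairing (unit excision) events in
    five flank-conservation classes, and classifies alternative-splicing
    modes (alternative acceptor, combined donor/acceptor, exon skipping)
    against exon/intron gene models. Includes a synthetic gene-family
    generator with complete ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    readr,
    ape,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
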