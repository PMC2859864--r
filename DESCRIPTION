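Package: flcdna
Title: Curation and Structural Annotation of Full-Length cDNA Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the classical full-length cDNA
    curation workflow used for plant cDNA collections: read trimming and
    filtering, EST clustering with 5'-most representative selection,
    redundancy collapse, non-coding RNA and pathogen contaminant filters
    with a host-rescue rule, chimeric-clone detection at restriction
    ligation sites, retained-intron screening by bidirectional spliced
    alignment, ORF enumeration with homology-ranked CDS selection and UTR
    annotation, transcript-to-genome gene models with exon typing and
    exon/intron statistics, alternative-splicing event classification, and
    exon-restricted nucleotide-mismatch (SNP) rate estimation. Includes a
    Smith-Waterman/Karlin-Altschul search layer, an est2genome-style
    spliced aligner, and a seeded synthetic-data generator with complete
    truth tables so every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
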