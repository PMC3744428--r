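Package: coopcis
Title: Cooperativity-Resolved Analysis of Transcription Factor Cistromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies transcription-factor ChIP-seq binding peaks by which
    p53 cooperativity genotypes occupy them using a rank-gap presence-calling
    rule, scans peak sequences for spacer-tolerant RRRCWWGYYY response
    elements, annotates peaks to nearest genes and genomic regions,
    integrates binding with expression fold-changes, compares peak sets
    across studies under a one-base-pair overlap rule, and stratifies
    patient survival by single-sample gene-set enrichment with a
    Monte-Carlo random-signature null. Includes a synthetic-data generator
    that emulates the statistical structure of a cooperativity-mutant
    cistrome study so every stage of the pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    survival,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
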