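Package: isoforge
Title: Reference-Guided Isoform Classification, Splicing Events and
    Tissue-Specificity Statistics for Full-Length Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for updating a genome annotation from full-length
    (long-read) transcript models: classification of query transcripts
    against a reference annotation into known isoforms, novel isoforms and
    new genes using exon-chain boundary-tolerance and exonic-overlap rules;
    detection of the seven local alternative-splicing event classes (SE,
    MX, A5, A3, RI, AF, AL); long non-coding RNA nomination from
    coding-potential votes and positional classification (lincRNA,
    antisense, sense intronic, sense overlapping); expressed-gene counting,
    differential-expression selection rules for tissue-specific genes and
    pairwise DEG unions; tissue/isoform specificity and entropy statistics
    with paired tests for ohnolog gene pairs across subgenomes; and seeded
    synthetic-data generators with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
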