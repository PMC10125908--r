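Package: splicefx
Title: Splicing Aberration Calling from SpliceAI Delta Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Interprets SpliceAI delta scores and delta positions for
    single-nucleotide variants into predicted splicing aberrations:
    pseudoexonization, partial intron retention, partial exon deletion,
    single- and multi-exon skipping, and whole intron retention. Computes
    exact inserted and deleted sizes against native splice sites of a
    reference transcript, rebuilds the altered coding sequence, determines
    the reading-frame effect, translates the altered protein with a
    bracketed change notation, and flags predicted nonsense-mediated decay
    or protein truncation. Includes a deterministic synthetic-fixture
    generator (toy genomes, transcripts, forged SpliceAI VCFs) and a
    benchmark harness for sensitivity/specificity evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    generics,
    ggplot2,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
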