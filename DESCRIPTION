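Package: isoscope
Title: Full-Length Transcript Characterization for Long-Read Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing full-length transcript isoforms from
    long-read (Iso-Seq style) genome alignments against a reference
    annotation: quality filtering and redundancy collapse with 5'-degradation
    tolerance, eight-category structural classification, alternative-splicing
    mode calling (intron retention, exon skipping, alternative donor/acceptor,
    mutually exclusive exons), rule-based fusion transcript detection with
    short-read validation, a long non-coding RNA filtering cascade with
    positional classification, splice-junction support scoring against
    short-read junction evidence, cytosine methylation metaprofiles at splice
    sites and over gene bodies, and rarefaction analysis. Includes a
    synthetic-data generator that emits a toy genome, annotation, reads,
    fusion alignments, junction evidence and methylation calls with fully
    known planted ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
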