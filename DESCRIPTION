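Package: junctionr
Title: Junction-Query Detection of Transcript Isoform Expression in RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds exon-exon junction query sequences from transcript models,
    scores RNA-seq reads against them with a local aligner under explicit
    query-cover and identity filters, and calls each transcript isoform as
    fully, partially or not supported per sample, flagging junctions whose
    read support is shared between isoforms. Includes a deterministic
    synthetic-data module (surrogate genome and junction-spanning read
    simulator over the 21q22.13 span of the KCNJ6/DSCR4 locus) so the whole
    pipeline runs at desk scale, plus a PCR primer-pair QC utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
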