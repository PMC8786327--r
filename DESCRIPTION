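Package: dilncseq
Title: Quantifying Break-Induced Antisense Transcription from
    Polymerase-Specific NET-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for nascent elongating transcript
    sequencing (NET-seq) analysis of antisense transcription induced by DNA
    double-strand breaks. Provides a generative simulator for
    polymerase-specific NET-seq libraries (promoter-proximal pausing,
    benzonase footprints, cytoplasmic contamination, immunoprecipitation
    enrichment, break-induced antisense transcription), an exact-match
    short-read aligner with reproducible random assignment of perfect
    multi-mappers, strand-resolved locus quantification (antisense fraction
    and reads-per-million statistics, IP/input recovery ratios), the
    replicate-level hypothesis tests applied to these statistics, and a
    scanner for RNA polymerase III terminator signals with read-density
    comparison across candidate terminators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    data.table,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
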