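Package: ReadQC
Title: Streaming Quality-Control Statistics, Trimming and Coverage Summaries for Illumina Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A self-contained quality-control stack for paired-end Illumina
    sequencing data. Provides a streaming FASTQ statistics engine (read and
    base counts, Q20/Q30 bases, length and quality ranges, base composition,
    GC content, read-length distributions) for plain or gzip-compressed
    files with phred offset 33 or 64; a sliding-window quality trimmer for
    read pairs with singleton routing; a genome-coverage breadth summarizer
    for zero-inclusive bedgraph tracks; a batch-parallel quick-QC pipeline
    producing before/after-trim reports over many samples; and a seeded
    paired-read simulator for generating test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
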