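Package: ribopipe
Title: Ribosome Profiling Read Processing, QC and Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing core for ribosome profiling (riboseq) experiments
    against an ORF-centric transcriptome reference. Trims sequencing
    adapters, removes rRNA contaminants by exact k-mer matching, aligns
    footprints to transcripts (built-in exact aligner or SAM/BAM ingestion),
    and stores per-gene read-length by 5'-position count matrices in HDF5.
    Provides A-site offset assignment, reading-frame and three-nucleotide
    periodicity diagnostics, start/stop metagene profiles, read-length and
    positional distributions, position-specific nucleotide frequencies,
    RPKM quantification, rank correlations of expression against sequence
    features, and relative abundance against a reference dataset panel.
    Includes a synthetic-data generator with per-read truth tables so every
    stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rhdf5,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
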