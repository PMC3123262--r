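Package: cghintegrity
Title: Genome Integrity Assessment from Array CGH Log2-Ratio Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing genome integrity of cell lines with
    high-density array comparative genomic hybridization (CGH). Implements
    penalized least-squares change-point segmentation of per-probe
    log2-ratio tracks, copy-number event calling under an explicit
    (log2 shift, consecutive probe count) criterion, calibration of that
    criterion against self-self (null) hybridizations, cross-hybridization
    triage of shared events, GC-content artifact analysis of called
    regions, and minimal chain-file interval remapping between genome
    assemblies. A synthetic-data generator produces genomes, probe maps
    and hybridization tracks with planted copy-number variants,
    GC-correlated baseline waves and dye bias, so the whole pipeline is
    testable end to end without microarray data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
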