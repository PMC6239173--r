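Package: teSmallRNA
Title: Simulation and Analysis of Transposon-Targeting Small RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of small RNA sequencing libraries that
    target transposable elements (TEs) in somatic tissue: a seeded simulator
    of small RNA libraries with planted ground truth (size-structured siRNA,
    piRNA-like and degradation classes, ping-pong pairing, tissue-specific
    miRNA profiles, A-to-G editing, contamination mixing), a short-read
    aligner with one-mismatch bowtie-like semantics (all, unique and
    random-one multimapper handling), ping-pong 5'-overlap signature scoring
    and library classification, gonadal-contamination detection by spike-in
    simulation and miRNA differential-abundance signatures, strand- and
    size-resolved TE siRNA quantification with counts-per-10-million filters
    and median-of-ratios normalization, ADAR editing mismatch spectra, and
    piRNA-cluster-exclusive read partitioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
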