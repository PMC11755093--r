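Package: trellisdna
Title: Trellis Soft Decoders for Nanopore DNA Data Storage
Version: 0.1.0
Authors@R:
    person("Trellis", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Encoders and decoders for hash-based constrained convolutional
    (HEDGES-style) DNA and RNA data storage read out on nanopore sequencers.
    Provides the constrained encoder with homopolymer and GC-window
    constraints, a best-first hard decoder over basecalled reads, two soft
    decoders that consume basecaller CTC (connectionist temporal
    classification) log-probability matrices directly -- a beam trellis
    decoder and an alignment-matrix trellis decoder based on incremental CTC
    forward variables -- together with a synthetic CTC matrix simulator,
    buffer trimming and orientation detection, CRC-based demultiplexing, and
    a Reed-Solomon outer-code model that converts byte error rates into
    storage densities in bits per base.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
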