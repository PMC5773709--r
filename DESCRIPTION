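Package: gfmap
Title: Alignment-Free Genome Comparison with Circularised Fingerprint Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transforms genome assemblies into circularised three-dimensional
    cumulative nucleotide walks ("genome-fingerprints maps"), compares
    assemblies map-to-map instead of base-to-base, computes a weighted
    eigen-angle distance matrix for alignment-free phylogenetics, detects
    composition-biased straight-line segments on the maps, excises them
    (proofreading errors-deletion), and provides tandem-repeat bookkeeping
    (core-unit nomenclature, motif scanning, interval arithmetic) plus a
    seeded synthetic-genome generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
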