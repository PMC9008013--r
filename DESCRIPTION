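Package: cenfuse
Title: Centromeric Satellite Architecture and Robertsonian Fusion Provenance
Version: 0.1.0
Authors@R: person("R.", "Carter", email = "rcarter.dev@posteo.net",
    role = c("aut", "cre"))
Description: Tools to characterize centromeric satellite DNA arrays and to
    trace the origin of Robertsonian (centric) fusion chromosomes from their
    donor centromeres. Detects full-length satellite monomers by iterative
    local alignment against a reference repeat unit, decomposes monomer
    arrays into higher-order-repeat-like blocks, infers block provenance by
    strand-aware consensus homology, scans degenerate (IUPAC) CENP-B box
    motifs, summarizes transition/transversion substitution spectra with a
    saturation assessment, and builds neighbor-joining trees from p-distances.
    Includes a seeded simulator of satellite arrays and fusion chromosomes
    with full ground truth for validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
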