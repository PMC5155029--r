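Package: bcrmrd
Title: B-Cell Receptor Repertoire Networks and Minimal Residual Disease Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of B-cell receptor (BCR) heavy-chain repertoire sequencing
    for B-cell acute lymphoblastic leukemia (B-ALL). Builds single-mismatch
    sequence networks to call clonality against a healthy background, defines
    clonotype signatures from index samples and mines longitudinal samples for
    minimal residual disease (MRD) within a mismatch budget, detects secondary
    IgHV rearrangements through shared D-J "stem" sequences, reconstructs clone
    phylogenies by maximum parsimony around the central BCR, and tests
    diagnosis-relapse repertoire overlap with exact hypergeometric statistics
    and 96-context trinucleotide mutation profiles. A seeded synthetic
    repertoire simulator (germline segments, V(D)J recombination, somatic
    hypermutation with AID hotspots, dilution series, sequencing error)
    provides ground-truth test substrates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    igraph,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse,
    jsonlite
Config/testthat/edition: 3
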