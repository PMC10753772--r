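Package: plastocomp
Title: Comparative Analysis of Reduced Plastid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative analysis of plastomes from closely
    related plant lineages, motivated by the strongly reduced, inverted-repeat
    lacking plastid genomes of hemiparasitic Cassytha (Lauraceae). Calls the
    mutation spectrum from a whole-plastome multiple alignment (substitutions,
    SSR and non-SSR indel events, hairpin-flanked micro-inversions), scans
    sliding-window nucleotide diversity for divergence hotspots, computes
    pairwise p-distance matrices, compares a reduced plastome against a
    quadripartite reference (inverted-repeat detection, missing gene segments,
    pseudogene calls), and checks species-level grouping with neighbor-joining
    trees. Includes a synthetic plastome generator that plants a known mutation
    and structural-reduction ledger, so every stage can be validated against
    ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
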