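Package: paleovir
Title: Discovery, Reconstruction and Dating of Endogenous Viral Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale paleovirology toolkit for endogenous viral
    elements (EVEs) derived from plant pararetroviruses
    (Caulimoviridae). Finds virus-derived intervals in host genome
    assemblies by seeded translated and nucleotide homology search,
    reconstructs ancestral circular virus genomes from decayed,
    fragmented insertions by tolerant anchored assembly and per-column
    majority consensus, annotates open reading frames and polyprotein
    domains (MP-CP-AP-RT-RH1), demarcates virus species and classifies
    bipartite A/B genome components, quantifies the integration
    landscape (genome occupancy, feature distances, intron overlap,
    (TA)n-repeat proximity enrichment against a randomized null, flank
    redundancy, nested-insertion joining, exact-match small-RNA
    mapping), and dates insertions by ortholog sharing on a calibrated
    ultrametric species tree under single-gain (Dollo) parsimony.
    A synthetic-data module simulates ancestral virus genomes,
    endogenization with ground-truth provenance, and ortholog
    gain/loss histories so the whole pipeline is testable end to end
    without external assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
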