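Package: repeatscape
Title: Repeat Landscape Simulation, Discovery, Annotation and Dating for
    Clone-Scale Genome Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the repetitive fraction of large plant
    genomes from clone-scale sequence surveys (BACs or scaffolds). Includes
    a forward simulator that plants transposable-element families, LTR
    retrotransposons, microsatellites and AT-rich low-complexity tracts
    into background sequence with full ground truth; a canonical k-mer
    occurrence index with low/mid/high repetitiveness classification of
    clones; de novo repeat interval calling, single-linkage family
    clustering and consensus building; homology masking against a labelled
    repeat library with overlap resolution and composition summaries;
    perfect SSR and low-complexity detection with strand/rotation
    canonical motifs; Kimura 2-parameter divergence with LTR-pair and
    consensus-based insertion-age estimation; a one-sample runs test of
    the spatial randomness of repeats along scaffolds; and Poisson-corrected
    neighbor-joining trees with bootstrap support for reverse-transcriptase
    domains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    ape,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
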