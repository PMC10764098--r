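Package: numtkit
Title: Detection, Characterization and Synteny-Based Orthology of Nuclear
    Mitochondrial Segments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying nuclear mitochondrial DNA segments (NUMTs)
    across genomes: calling NUMTs from tabular mitogenome-versus-nuclear
    alignment hits, assembling NUMT blocks, testing for nonrandom mtDNA
    origin with sliding-window rank tests and a circular reshuffling null,
    profiling transposable-element and genic context, classifying open
    reading frames under nuclear and vertebrate-mitochondrial genetic
    codes, assigning cross-species NUMT orthology by genome microsynteny
    with an analytic false-assignment model, and reconstructing ancestral
    NUMTs and per-lineage insertion rates on a time-calibrated phylogeny.
    Includes a truth-annotated forward simulator of NUMT gain, loss and
    decay along a species tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    BiocGenerics,
    ape,
    igraph,
    jsonlite,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
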