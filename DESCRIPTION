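Package: spacerscope
Title: CRISPR Spacer Repertoire Profiling for Thermophile Communities
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative profiling of CRISPR spacer repertoires from
    repeat-anchored amplicon sequencing of environmental bacterial
    communities. Locates IUPAC-degenerate repeat consensi in reads and
    genomes, extracts spacers between adjacent same-type repeats, collapses
    them into identity clusters with abundance-ranked centres, computes
    alpha/beta diversity and cross-site sharing of repertoires, reconstructs
    CRISPR array fragments from spacer adjacency in multi-spacer reads, and
    maps spacers onto phage genomes to infer protospacer adjacent motifs
    (PAMs), targeting locality and strand bias. Ships a ground-truthed
    synthetic community and read simulator so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
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
    vegan,
    ape,
    igraph,
    jsonlite,
    yaml,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Metagenomics, SequenceMatching, Clustering, Microbiome
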