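Package: founderpan
Title: Founder Sequences, Kernel Indexing and Ad Hoc References for
    Pangenomic Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds a reference-guided multiple sequence alignment from
    phased VCF variants through a per-chromosome directed acyclic variant
    graph, reconstructs a small set of founder sequences by optimal
    bridge-node segmentation and greedy bipartite joining, excises long
    repeated phrases from the founders into an LZ77-compatible kernel
    sequence for read alignment, extracts a heaviest-path ad hoc reference
    from read support over the founder alignment, and projects variants
    called against the ad hoc reference back to original reference
    coordinates, reporting ad-hoc-embedded variants with ploidy-aware
    genotypes.  Includes a generational single-nucleotide mutation
    simulator and a paired-end read simulator with truth alignments for
    self-contained evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    SummarizedExperiment,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    VariantAnnotation,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
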