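Package: tandemtrace
Title: Tandem Gene Family Evolution from Intergenic Homology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the evolutionary history of expanded
    gene families in genome assemblies. Implements overlap (free end gap)
    Needleman-Wunsch alignment with affine gap costs and PID3 percent
    identity, segmentation of tandem gene loci into flank, genic and
    intergenic regions, dating of tandem duplications from residual
    intergenic homology against a shuffle null, domain-architecture gene
    family classification with catalytic-motif auditing, phylogeny-based
    transposition inference from bootstrap-supported monophyly across
    unlinked loci, telomere-based minimum chromosome counting, CAZyme
    profile normalization and Bray-Curtis clustering, bit-score-binned
    homolog sampling, and a ground-truth genome-evolution simulator
    (unequal crossing over, transposition, domain events, Jukes-Cantor
    drift) that exercises the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    phangorn,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
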