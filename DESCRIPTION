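Package: fgiTyper
Title: Detection and Typing of Flagellin Glycosylation Islands in
    Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for locating the flagellin glycosylation island (FGI)
    that integrates between the flagellin gene flaA2 and flaG in the
    flagellar biosynthetic locus of Geobacillus and related Firmicutes.
    The package extracts the intergenic island from annotated genomes,
    computes compositional evidence of horizontal acquisition (island
    versus genome G+C content), calls FGI-positive/negative status from
    glycosyltransferase and maf gene content, clusters island proteins
    into ortholog families by global alignment identity, and types
    islands by Pearson correlation of binary presence/absence profiles
    followed by UPGMA clustering with a similarity cutoff.  A synthetic
    genome generator with known ground truth supports end-to-end
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    ape,
    igraph,
    jsonlite,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
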