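Package: ribdtools
Title: Bidirectional Introgression Scanning with Relative IBD, D and f_d Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects bidirectionally introgressed genomic regions between two
    diverged domestic populations, each with a conspecific wild background
    population and a distant outgroup. Implements pairwise haplotype
    identity-by-descent detection and windowed relative IBD (rIBD), windowed
    Patterson's D and f_d with direction inference via two population
    arrangements, segment calling with bidirectional intersection,
    permutation-based F_ST tests for population-stratified structural
    variants with flanking-segment classification, SV-SNP linkage tagging,
    and locus-level haplotype frequency and network summaries. Ships a
    forward-in-time admixture-pulse simulator with exact donor-tract
    bookkeeping for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Rcpp,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
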