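Package: ssrscape
Title: Genomic Landscape and Population Genetics of Simple Sequence Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Survey of perfect simple sequence repeats (microsatellites) in
    annotated genomes and population-genetic comparison of SSR loci by
    genomic context. Detects perfect 1-6 bp tandem repeats at MISA-style
    thresholds with rotation/reverse-complement motif canonicalization,
    partitions scaffolds into nine positional categories relative to gene
    models (exon, intron, UTRs, near and far flanks, distal), computes
    size-standardized SSR densities, a chi-square test of non-random
    placement, and gene-term over-representation. For haploid multilocus
    microsatellite genotypes it computes allelic diversity, allele-difference
    distances, three-level haplotypic AMOVA with Phi-statistics and
    permutation tests, per-locus Fst and island-model gene flow, principal
    coordinates analysis, and variance-ratio comparisons across locus
    categories. Includes simulators for annotated genomes with planted SSRs
    and for two-species populations under a bounded stepwise mutation model,
    providing ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    ggplot2,
    withr
Config/testthat/edition: 3
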