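Package: clonepop
Title: Population Genomics and Epigenomics of Facultatively Clonal Plant
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genomic and population-epigenomic analysis
    of facultatively asexual (clonally propagating) plants. Provides a
    variant-filtering cascade with ordered per-rule attribution, clonal-family
    detection from pairwise genotype distances, nucleotide diversity (pi,
    piN/piS with Nei-Gojobori site counting), Tajima's D, genotype-based
    linkage-disequilibrium decay, selective-sweep scans (background-SFS
    composite likelihood ratio and a mu-type composite statistic), a
    three-population branch-specific CLR scan from linked allele-frequency
    differentiation, permutation nulls for gene-family enrichment, binomial
    methylation calling with weighted methylation levels from bisulfite
    cytosine reports, and rejection-ABC demographic model choice. A built-in
    coalescent simulator of partially clonal populations (effective
    recombination scaled by the fraction of sexual generations) generates
    genotype matrices and VCF/GFF3/FASTA/BED/cytosine-report fixtures with
    ground-truth records for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    igraph,
    vcfR,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
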