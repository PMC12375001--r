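Package: duripop
Title: Population Genomics of a Diploid SNP Panel: Diversity, Structure,
    Sweep Scans and Core Collections
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-variant-calling population-genomic analysis of diploid
    biallelic SNP panels, built around a durian (Durio zibethinus)
    germplasm resequencing design of 114 accessions in three populations.
    Provides VCF/GFF3/FASTA/TSV input and output, missingness and minor
    allele frequency filtering, windowed nucleotide diversity, Watterson's
    theta and Tajima's D, Weir-Cockerham Fst (ratio-of-sums), pi-ratio and
    reduction-of-diversity (ROD) tracks, linkage disequilibrium decay
    curves, principal component analysis, admixture-model fitting by EM
    with cross-validated choice of K, neighbor-joining phylogenies with
    SNP bootstrap support, variant effect classification into
    HIGH/MODERATE/LOW/MODIFIER impact classes, joint Fst x ROD
    selective-sweep scanning with gene intersection, and greedy
    core-collection construction by allele-coverage maximization.
    A synthetic-panel generator (Balding-Nichols populations with
    distance-decaying LD, planted sweeps and random gene models) and a
    neutral coalescent locus simulator make every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    ape,
    vcfR,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
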