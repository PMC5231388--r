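Package: ldenrich
Title: Covariate-Modulated Polygenic Enrichment of GWAS Summary Statistics
    in LD-Weighted Annotation Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether genome-wide association signal is
    enriched in annotation categories (evolutionary regions such as human
    accelerated regions, segmental duplications and ohnologs; genic parts;
    gene sets) after accounting for linkage-disequilibrium (LD) and
    genic-category confounding. Computes per-SNP LD-weighted region
    affiliation scores and total-LD burden from a reference genotype panel,
    estimates genomic-control inflation from intergenic SNPs via repeated LD
    pruning, draws conditional fold-enrichment (stratified QQ) curves,
    quantifies enrichment by partial least squares regression of squared
    association z-scores with jackknife approximate t-tests over LD-aware
    cross-validation folds, and samples LD/MAF-matched null SNP sets. A
    synthetic-data generator (block-LD panel, annotation tracks, summary
    statistics under a polygenic model with planted per-annotation
    enrichment) makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    jsonlite,
    igraph,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    mixOmics,
    ggplot2
Config/testthat/edition: 3
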