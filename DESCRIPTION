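Package: nerkascan
Title: Population-Genomic Scans for Sockeye Salmon and Kokanee Resequencing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the population-genomic analysis
    layer used in whole-genome resequencing studies of sockeye salmon and
    kokanee (Oncorhynchus nerka): successive variant filters (biallelic
    SNP/missingness/MAF, a heterozygous allele-balance filter targeting
    collapsed paralogs, and LD pruning), standardized-genotype PCA with
    BIC-selected k-means clustering, eigenvector genome scans with
    genomic-inflation correction and proximity-cluster peak calling,
    logistic-regression trait association with max-statistic permutation
    thresholds, genotype r-squared linkage-disequilibrium statistics, and
    per-individual diversity metrics (heterozygotes per kbp, heterozygosity
    ratio, runs of homozygosity). A Balding-Nichols multi-population cohort
    simulator with planted divergent haploblocks, allele-balance artifact
    sites and a presence/absence sex marker makes every stage exercisable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
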