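Package: conifergp
Title: Genome-Wide Association and Genomic Prediction for Unrelated Conifer Plus-Tree Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide studies of unrelated plus-tree breeding
    populations genotyped on SNP arrays: quality control and EM imputation of
    -1/0/1 genotype scores, linkage-disequilibrium profiles on a genetic map,
    expected and observed heterozygosity, admixture estimation with a
    cross-entropy criterion and the per-genotype effective number of clusters,
    realized-relationship kinship and genotype PCA, clonal-value estimation
    from replicated field trials by REML mixed models, kinship- and
    PC-adjusted single-marker association scans with FDR control and
    cross-population region detection, genomic prediction by GBLUP, BayesB and
    random-forest regression under replicated cross-validation, and
    GWAS-based versus semi-random low-density SNP panel selection. A seeded
    synthetic-cohort generator emulating admixed multi-population array data
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
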