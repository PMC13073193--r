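Package: t1dnn
Title: Neural-Network Polygenic Risk Modelling and Stratification for Type 1 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a compact-panel polygenic risk pipeline for type 1
    diabetes built around a feed-forward neural network classifier. Provides
    the 67-SNP GRS2 variant panel with risk alleles and beta weights, genotype
    ingestion from VCF or dosage matrices with orientation to risk-allele
    dosages, Hardy-Weinberg imputation of missing genotypes from a
    prevalence-controlled reference, per-subject genotype-entropy features,
    nested case-control undersampling with stratified cross-validation and
    grid search, a linear beta-weighted genetic risk score benchmark, AUC with
    DeLong confidence intervals, and a five-category prevalence-aware risk
    stratification framework. A synthetic-cohort generator with a logistic
    liability model makes every stage testable without restricted genotype
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
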