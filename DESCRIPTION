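Package: snpLasso
Title: Penalized Regression for Phenotype Prediction from SNP Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for genome-enabled prediction
    of a quantitative trait from SNP dosage data. Provides
    heritability-parameterized genotype and phenotype simulators, PLINK 1
    binary and TSV dosage input/output, SNP-level quality control (minor
    allele frequency and exact Hardy-Weinberg tests), construction of an
    analysis phenotype from repeated triglyceride measures with covariate
    and genotype principal-component adjustment, single-SNP association,
    greedy LD-based clumping, a coordinate-descent LASSO solver with
    regularization-path warm starts and KKT certification, and nested
    k-fold cross-validation for penalty selection and out-of-sample
    evaluation of predictive performance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, SNP, Regression, GenomePrediction, StatisticalMethod
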