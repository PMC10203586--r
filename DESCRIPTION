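Package: phenogs
Title: Phenomic and Genomic Yield Prediction in Multi-Environment Wheat Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for phenomic selection studies in
    multi-environment cereal trials. Generates synthetic biparental and
    three-way cross populations with bulk-sampled SNP dosages, alpha-lattice
    style trial designs, genotype-by-environment interaction and redundant
    plot-level trait panels (multispectral, hyperspectral, visual, soil).
    Implements the downstream prediction pipeline: marker quality control
    (PIC filtering, correlation pruning), trait redundancy analysis and
    dimensionality reduction (PCA, PLS), EM-REML variance components and
    BLUEs for incomplete block designs, univariate and multivariate GBLUP,
    penalized regression (lasso, elastic net, ridge) by coordinate descent,
    and a masking/resampling engine reporting prediction accuracy as squared
    correlations under within-location fraction grids, whole-location
    leave-out and training-set supplementation schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    lme4,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'evaluation.R'
    'io.R'
    'marker-qc.R'
    'mixed-models.R'
    'penalized.R'
    'pipeline.R'
    'simdata.R'
    'trait-reduction.R'
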