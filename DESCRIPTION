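Package: widlo
Title: DNA Methylation Index of Cervicovaginal Microbiome Community State
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives a DNA-methylation signature (the WID-LO index and its
    nonlinear variant) that classifies a cervicovaginal microbiome as
    Lactobacilli-dominated (L) or not (O) from beta-value methylomes of
    cervical smear samples. Provides beta-level quality control (detection
    p-value masking, sample and probe failure filtering, probe exclusion
    lists, k-nearest-neighbour imputation), robust reference-based cell-type
    deconvolution into epithelial, fibroblast and immune fractions, five
    per-CpG ranking statistics (adjusted logistic regression, Welch, Bartlett,
    delta-beta intercept extrapolation, cell-type interaction models) with
    geometric-mean rank aggregation, an elastic-net feature-pool scan under
    cross-validation, Firth bias-reduced logistic association models, ROC
    evaluation with DeLong and stratified-bootstrap confidence intervals,
    CpG-annotation enrichment, and a synthetic-cohort generator that emulates
    the cell-type-mixture structure of cervical-smear methylomes with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, Microbiome, Classification
RoxygenNote: 7.3.3
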