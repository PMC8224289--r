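Package: mcicps
Title: Subtype-Based Multi-Modal Prediction of Conversion from Mild
    Cognitive Impairment to Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a subtyping-based strategy for predicting
    three-year conversion from mild cognitive impairment (MCI) to
    Alzheimer's disease from three data modalities: SNP genotypes, blood
    gene expression and structural-MRI regional brain volumes. Patients
    are clustered into molecular subtypes by similarity network fusion
    of the genotype and expression layers with RatioCut spectral
    clustering; new patients are assigned to a subtype by semi-supervised
    label propagation over the fused patient network. Within each
    subtype, conversion-informative features are selected per modality by
    repeated class-balanced undersampled Lasso with enhanced dual polytope
    projection (EDPP) safe screening, and conversion is predicted by a
    variational-Bayes multinomial-probit multiple-kernel classifier over
    a convex combination of per-modality Gram matrices. Includes genotype
    quality control, intracranial-volume adjustment of regional volumes,
    a synthetic multi-modal cohort generator with known ground truth,
    cross-validation and external-validation evaluation with ROC/AUC
    metrics, and Gini-impurity feature importance from a bagged tree
    ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
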