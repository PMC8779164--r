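Package: mtreg
Title: Multinomial Tensor Regression for 3D Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits multinomial (softmax) logistic regression models in which
    the coefficient array for a three-dimensional image covariate is
    constrained to a low-rank CP (CANDECOMP/PARAFAC) decomposition, so that
    whole-brain structural MRI volumes can be used directly as predictors of
    a categorical diagnosis.  Estimation is by maximum likelihood using a
    block-relaxation scheme whose blocks are the CP component vectors, each
    updated with the Adam optimizer; the learning rate can be tuned by
    stratified cross-validation.  Includes multi-class evaluation metrics
    (prediction accuracy, Rand index, and the Hand-Till multi-class AUC),
    a synthetic-data generator with planted low-rank signals for validation
    and parameter-recovery studies, NIfTI volume ingestion, export of
    coefficient surfaces that localize discriminative image regions, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
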