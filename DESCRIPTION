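Package: nodebag
Title: Attention-Guided Multiple Instance Learning for Lymph Node
    Metastasis Prediction from CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts lymph node metastasis from preoperative CT by treating
    each patient as a bag of visible lymph nodes and learning an
    attention-pooled bag classifier, alongside radiomic, deep-feature and
    clinical sub-models fused by a stacking ensemble. Includes CT volume
    standardization and patch extraction, a compact radiomic feature
    catalog (shape, first-order, GLCM, GLRLM, GLSZM, GLDM, NGTDM), the
    z-score/Spearman/ICC/LASSO feature-reduction chain, ROC and
    decision-curve evaluation with Youden cutoffs, and risk-stratified
    survival decision support for postoperative adjuvant therapy, all
    exercisable end-to-end on synthetic cohorts and phantom volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    survival,
    pROC,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
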