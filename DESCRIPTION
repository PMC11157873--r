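Package: radcombat
Title: ComBat Harmonization and Evaluation of Multi-Scanner CT Radiomic Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying scanner-manufacturer batch effects in CT
    radiomic feature tables. Implements parametric empirical-Bayes ComBat
    location/scale harmonization with protected covariates, a synthetic
    multi-scanner feature and texture-phantom generator with known ground
    truth, IBSI-style first-order and texture-matrix features (GLCM, GLRLM,
    GLSZM, GLDM), lasso feature screening, batch-effect assessment by
    per-feature one-way ANOVA and PCA, and a five-model classification
    harness comparing performance before and after harmonization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    ranger,
    e1071,
    pROC,
    RNifti,
    jsonlite,
    yaml,
    withr,
    cluster
Suggests:
    testthat (>= 3.0.0),
    sva,
    optparse
Config/testthat/edition: 3
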