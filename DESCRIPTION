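Package: bmradiomics
Title: Radiomics of Bone-Marrow Biopsy Sites in FDG PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether the marrow sampled at a bone-marrow biopsy
    site (sternum or posterior iliac crest) is representative of whole-bone-marrow
    measurable residual disease on [18F]FDG PET/CT. Provides rule-based CT
    segmentation of the whole bone marrow and of the three standard biopsy sites,
    uniform SUV quantization, a 32-feature radiomic panel (histogram, GLCM, GLRLM,
    NGTDM plus SUVmax/SUVmean), group-difference and correlation screening with
    Benjamini-Hochberg correction, Safe-Level-SMOTE oversampling and a
    cross-validated eight-classifier suite, together with a synthetic PET/CT
    phantom cohort generator with ground-truth masks so the whole pipeline runs
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    e1071,
    rpart,
    randomForest,
    nnet,
    class,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
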