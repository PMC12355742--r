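Package: neurofuse
Title: Multimodal Fusion of Volumetric MRI and Clinical Features for
    Stroke Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts dichotomized post-stroke outcomes (prolonged length
    of stay, poor 90-day modified Rankin Scale) from volumetric
    diffusion-weighted MRI fused with tabular clinical features. Provides
    a synthetic lesion-phantom cohort generator, tabular preprocessing
    with leakage-safe train-only fitting, stratified shuffle splits, 3D
    convolutional networks (ResNet-10 with optional squeeze-and-excite,
    convolutional autoencoder, DAFT conditioned feature maps), an
    AUPRC-first experiment harness over clinical, image, and combined
    arms, threshold-free and thresholded evaluation metrics, and 3D
    Grad-CAM saliency with lesion-localization scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
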