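Package: FDCNet
Title: Fuzzy Deep Convolutional Networks with Morphological and
    Eigenimage Features for Tumor Detection in MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detection and classification of tumor-like objects in 2D and
    3D grayscale images. Implements landmark-based normalization and
    preprocessing (resizing, histogram equalization, median and high-pass
    filtering, de-rotation), set-theoretic binary morphology (erosion,
    dilation, boundary extraction) with a MAD-based spike threshold for
    edge-seeded segmentation, snapshot-PCA eigenimage feature extraction
    with Euclidean-distance matching, and a fuzzy deep convolutional
    network (FDCNet) that fuses a dilated-convolution branch with a
    Gaussian-membership fuzzy branch for three-class labeling (benign,
    malignant, suspicious). Ships a deterministic synthetic-phantom
    generator with ground-truth masks, the standard evaluation metrics
    (accuracy, sensitivity, MSE, PSNR, SNR, ROC/AUC), and a config-driven
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    tiff,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
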