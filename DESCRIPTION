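Package: glcmseg
Title: Hybrid Encoder-Decoder and GLCM Texture Segmentation of Brain Tumors in Multi-Modal MRI
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully tested implementation of a hybrid brain-tumor
    segmentation pipeline for multi-modal MRI (FLAIR, T1, T1ce, T2). A compact
    SegNet-style encoder-decoder network with max-pooling-index unpooling
    produces per-class score maps; a region of interest (ROI) covering the
    whole-tumor extent is predicted from the best single modality; windowed
    gray-level co-occurrence matrix (GLCM) texture features (angular second
    moment, contrast, correlation) are computed on T1ce inside the ROI; the
    fused 7-element per-pixel feature vectors are classified by a decision
    tree into edema, necrosis and enhancing tumor. Includes a synthetic
    multi-modal phantom generator with BRATS-style nested labels and
    region-specific textures, NIfTI-1 and grayscale PNG input/output, and a
    region-grouped F-measure evaluation harness (whole tumor, tumor core,
    enhancing tumor).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
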