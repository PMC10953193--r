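Package: lungrpn
Title: 3D Region Proposal Networks for Pulmonary Nodule Detection in Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and evaluating 3D region proposal networks
    for pulmonary nodule detection in chest CT. Provides MetaImage and NIfTI
    volume handling with isotropic resampling and Hounsfield-unit
    normalisation, synthetic lung phantoms with controllable nodule diameter
    and solid-component fraction, ResNet / ResNeXt / CSP-ResNeXt 3D backbones
    with an optional feature-pyramid neck and a dense anchor-based detection
    head, IoU-matching and nearest-anchor training-sample assignment,
    focal-loss training with the Ranger optimiser, sliding-window inference
    with 3D non-maximum suppression and lung masking, and FROC/CPM evaluation
    with k-fold aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, RNifti, stats, utils, yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
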