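Package: ctvseg
Title: Cascaded Anatomy-Guided Segmentation of Cervical Cancer Clinical
    Target Volume from 3-D MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully automated coarse-to-fine pipeline for segmenting the
    clinical target volume (CTV) in cervical cancer radiotherapy from 3-D
    T2-weighted MR volumes.  The cascade segments the bladder with a 3-D
    U-Net, estimates the CTV position from the bladder centroid (the CTV
    centre lies on average 39 mm posterior to the bladder centre), detects
    the superior-inferior CTV span slice-by-slice with a 2-D attention
    U-Net, and performs block-based 3-D segmentation with overlap fusion
    inside a CTV-specific region of interest.  Monte-Carlo dropout provides
    per-voxel uncertainty maps.  Includes a synthetic pelvic-phantom
    generator so that the whole pipeline can be trained and validated at
    desk scale, volumetric I/O for NIfTI and MetaImage, and 3-D evaluation
    metrics (Dice, 95th-percentile Hausdorff distance, absolute volume
    difference).  All network layers are implemented natively in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
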