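Package: fcseg
Title: Feature-Based Fuzzy Connectedness Segmentation for B-Mode Ultrasound
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of echogenic tissue layers in B-mode ultrasound
    images using absolute fuzzy connectedness with a contrast-invariant
    affinity built from the monogenic signal. Local phase and multi-scale
    feature asymmetry replace raw intensities in the affinity function, a
    curvature-scale (c-scale) shape descriptor detects and fills acoustic
    shadow gaps in the segmented object, and mean curvature flow regularises
    the final boundary. Includes regional entropy image-quality scores,
    region- and distance-based segmentation evaluation metrics, and a
    deterministic speckle phantom emulating a fetal arm cross-section for
    end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
biocViews: Software, Segmentation, ImageProcessing
RoxygenNote: 7.3.3
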