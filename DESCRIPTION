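Package: silkit
Title: Whole-Slide Assessment of Cervical Squamous Intraepithelial Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the tissue-level assessment of cervical squamous
    intraepithelial lesions (SIL) on whole-slide images: tiling of large
    rasters into fixed windows and lossless stitching of per-tile masks,
    skeleton-based partition of the squamous epithelium into vertically
    oriented patches along its medial axis, transfer of p16
    immunohistochemistry labels onto the H&E frame through a dense
    displacement field, diffuse-proportion lesion calling with configurable
    5%/10% thresholds, segmentation losses (cross-entropy, dice) and
    class-balanced sampling, and an evaluation suite (confusion metrics,
    ROC/AUC with DeLong confidence intervals, mask IoU). A deterministic
    color-interval segmentation backend and a paired H&E/IHC synthetic slide
    generator with exact ground truth make the full pipeline testable end to
    end without access to clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
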