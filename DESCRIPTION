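Package: musarch
Title: Muscle Architecture Measurement from Longitudinal Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for extracting skeletal-muscle architecture parameters
    from longitudinal B-mode ultrasound images: aponeurosis segmentation with a
    compact attention U-Net, mask refinement by connected-component analysis,
    skeletonization and quadratic bridging, centerline-based muscle thickness,
    unsupervised ridge-filter fascicle extraction, pennation angle and fascicle
    length estimation, and agreement metrics (Dice, IoU, ICC(2,1), RMSE,
    Bland-Altman). Includes a synthetic phantom generator with exactly known
    geometry for ground-truth validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
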