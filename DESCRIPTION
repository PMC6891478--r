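Package: poppydetect
Title: Single-Stage Detection of Opium Poppy Plots in UAV Imagery
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A CPU-scale implementation of an SPP- and GIoU-enhanced
    YOLOv3-style single-stage detector for locating opium poppy plots in
    large unmanned-aerial-vehicle (UAV) frames. Provides
    ground-sampling-distance camera geometry, Pascal-VOC dataset
    construction (object-centred cropping, oversampling balance,
    Beta-mixup fusion, randomized augmentation, train/val/test splits),
    a pluggable MobileNetv2-style backbone with a padded stride-1
    spatial-pyramid-pooling unit, a composite loss with a GIoU
    coordinate term, sliding-window tiled inference, precision/recall,
    AP50 and F2 evaluation, and a synthetic-scene generator standing in
    for field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
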