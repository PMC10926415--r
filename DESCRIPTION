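Package: blurtrack
Title: Detection, Tracking and Wingbeat Analysis of Insect Motion Blurs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for camera-based monitoring of low-flying nocturnal insects.
    Long-exposure night captures render flying insects as bright motion-blur
    streaks on a dark background; blurtrack detects those streaks with a
    classical robust-threshold detector, infers polyline annotations by
    polynomial regression on segmentation masks, tracks individuals across
    video frames by linking detections in pairwise maximum images with a
    linear-sum-assignment matcher on the endpoint matching distance, estimates
    wingbeat frequency from the periodic intensity modulation along a blur,
    and scores automatic annotations against ground truth (bounding-box IoU,
    polyline Hausdorff distance, length difference, precision-recall curves).
    Annotations are interchanged as VGG Image Annotator (VIA) version-2
    project JSON, and a seeded synthetic-scene generator provides
    ground-truthed fixtures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
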