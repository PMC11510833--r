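Package: yoloev
Title: Extended-Vision Single-Stage Object Detection for Weed and Crop Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds, profiles and trains the YOLO-EV family of single-stage
    object detectors: YOLOv8-style backbones (C2f, SPPF, decoupled anchor-free
    heads) extended with multi-branch group-enhanced fusion attention (MGEFA),
    large separable kernel attention (LSKA) in the pooling block, a fourth
    stride-64 (P6) pyramid level with a lightweight C2 neck, and the Wise-IoU
    bounding-box regression loss with its dynamic non-monotonic focusing
    mechanism.  Includes exact structural profiling (trainable parameters and
    GFLOPs), IoU-family losses, mean-average-precision evaluation, YOLO/VOC
    annotation input and output, a synthetic weed-scene generator, and a small
    CPU training loop built on an internal reverse-mode array engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
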