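Package: fundusXAI
Title: Auditing Saliency Explanations of Diabetic-Retinopathy Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for judging whether a fundus-image diabetic-retinopathy
    (DR) classifier attends to clinically relevant regions. Computes
    gradient-based attributions (Grad-CAM and Integrated Gradients) for any
    classifier exposed through a small adapter contract, binarizes the
    normalized heatmaps at method-specific percentiles, intersects the
    high-activation regions with per-lesion binary masks (microaneurysms,
    exudates, hemorrhages, neovascularization, optic disc, macula), counts
    overlap hits and IoU per DR grade and prediction correctness, and
    quantifies agreement between manual and automatic lesion-highlight
    assessments with Cohen's kappa. Ships a synthetic fundus-scene generator
    with ICDR-consistent grade labels and a fixed-weight differentiable
    fixture classifier so the whole pipeline is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    pROC,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
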