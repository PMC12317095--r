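Package: duetmil
Title: Dual-Modality Multiple-Instance Transformer for Whole-Slide Biomarker Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiple-instance learning on paired hematoxylin & eosin and
    immunohistochemistry whole-slide images for binary biomarker prediction
    (microsatellite instability, mismatch-repair deficiency, PD-L1 combined
    positive score). Implements a parameter-shared dual-branch transformer
    aggregator with branch dropout trained by cross-validated AdamW, tissue
    segmentation and tessellation utilities, a deterministic toy tile
    encoder, attention-rollout and contribution heatmaps, screening
    trade-off analysis, and claims-derived survival endpoints
    (time-on-treatment, overall survival) with Kaplan-Meier, log-rank and
    Cox analyses. Ships a synthetic paired-modality cohort generator so the
    full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    survival,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
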