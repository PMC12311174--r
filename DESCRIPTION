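Package: fusionmil
Title: Weakly Supervised Prediction of Rare Gene Fusions from H&E Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for predicting rare kinase gene fusions
    (ROS1, ALK, NTRK) from hematoxylin-and-eosin whole-slide images under
    weak, slide-level supervision. Provides sequential tissue masking and
    tiling, self-supervised contrastive pretraining of a tile encoder,
    transformer-based multiple-instance aggregation of tile feature bags,
    a two-step composite-label (RAN) pretrain-then-finetune training
    strategy with class-weighted loss, diagnostic-metric evaluation with
    PPA/NPA trade-off analysis, attention-rollout interpretability maps,
    and a synthetic slide and feature-bag generator so the whole pipeline
    is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
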