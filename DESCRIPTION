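Package: bcirisk
Title: Cognitive-State Risk Classification from Multimodal Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies users of brain-computer-interface (BCI) tasks into high- and
    low-risk cognitive-state classes from pupil dilation, blink rate and galvanic
    skin response (GSR). Implements baseline-ratio pupillometry, blink detection
    from eye-tracker sample gaps, per-second GSR normalization, per-task K-means
    clustering with silhouette-based choice of the cluster count, rule-based
    tagging of risky cognitive states, and combination with task performance into
    per-task and general risk classes. A consistency-validation suite re-derives
    the rule-based labels with logistic regression (IRLS with classification
    tables, Nagelkerke R-squared and omnibus test), a Gini CART tree, and a
    tanh/softmax feedforward network trained in batch, online or mini-batch mode.
    A calibrated synthetic-cohort generator produces raw signals with a known
    latent two-state structure so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
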