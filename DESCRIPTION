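Package: breathturn
Title: Respiratory Turn-Taking Analysis for Multiparty Conversation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of speech breathing and turn-taking in multiparty
    conversation from respiratory inductance plethysmography (RIP) traces
    and speech-activity annotations. Provides breathing-cycle segmentation
    with speaking-volume and resting-expiratory-level calibration,
    histogram-based breath-hold (plateau) detection, interaction-chronogram
    classification of interactional intervals (within- and between-speaker
    silences and overlaps, augmented by the presence of an inhalation in
    the previous speaker), kinematic feature extraction for inhalations
    and exhalations, detection of hidden conversational events (abandoned
    turn initiations, hold-conditioned speaker-change probabilities),
    multinomial logistic regression with stepwise likelihood-ratio
    predictor selection and McFadden's pseudo-R-squared, and a synthetic
    multiparty conversation generator with ground-truth labels for
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
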