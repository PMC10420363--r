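Package: gaitevents
Title: Gait Event Detection from Marker Trajectories with Recurrent
    Networks and Velocity Heuristics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects initial contact (IC) and foot off (FO) gait events
    from lower-limb motion-capture marker trajectories. Implements a
    frame-labelling detector based on stacked bi-directional LSTM
    networks (one independent model per event type) trained with a
    class-weighted cross-entropy loss, together with a velocity-threshold
    heuristic baseline in the style of Ghoussayni, peak-detection
    post-processing, tolerance-window event matching with temporal-error
    and detection-rate metrics, paired nonparametric method comparison,
    and a parametric synthetic-gait simulator that produces trials with
    construction-defined ground-truth events for end-to-end evaluation.
    Includes minimal C3D file input/output and a JSON fixture format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
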