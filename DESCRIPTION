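Package: romtrack
Title: Joint-Angle Tracking, Repetition Counting and Reliability
    Statistics for Lower-Limb Rehabilitation Exercises
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for video-derived lower-limb rehabilitation tracking
    from 33-keypoint pose landmark streams (BlazePose topology): joint
    angle extraction by the vector dot-product rule and the law of
    cosines, fuzzy rule-based exercise status bands, hysteresis-based
    repetition counting with per-repetition range-of-motion reporting,
    k-nearest-neighbour terminal-state pose classification with
    per-frame confidence traces, and the evaluation statistics used for
    angle validation and test-retest reliability (MAE, MSE, RMSE,
    coefficient of determination, ROM summaries, intraclass correlation).
    Includes a forward-kinematic generator of seated lower-limb exercise
    landmark sequences with known ground truth, so the whole pipeline is
    testable without access to clinical video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    class
Config/testthat/edition: 3
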