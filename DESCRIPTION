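Package: paplay
Title: Free-Living Physical Activity Classification for Preschool Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying the free-living physical activity of
    preschool-aged children from raw tri-axial accelerometer data annotated by
    direct observation. Provides readers for accelerometer streams and
    observation event logs, non-overlapping window segmentation with
    majority-rule labels and mixed-window flags, time- and frequency-domain
    feature extraction (including lag/lead temporal features), random-forest
    activity classifiers for hip, wrist and combined placements,
    leave-one-subject-out cross-validation with per-class and weighted
    F-scores and confusion matrices, and a bout-structured free-play
    simulator so the whole pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    randomForest,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
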