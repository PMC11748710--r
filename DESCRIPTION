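Package: octgrade
Title: Explainable Nuclear Cataract Grading from AS-OCT Nucleus Histograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades nuclear cataract severity (normal, mild, severe) from
    anterior-segment optical coherence tomography (AS-OCT) images using an
    explainable pipeline: pixel-intensity histograms of the segmented lens
    nucleus, a catalog of 27 histogram- and intensity-based visual features,
    feature importance by retraining-based Shapley values combined with
    Pearson-correlation redundancy filtering, and an ensemble of one-vs-all
    ridge regression models combined by softmax. Includes a seeded generator
    of synthetic AS-OCT-like nucleus images so the full pipeline can be
    exercised and validated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
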