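Package: divetrace
Title: Inferring Seabird Dives from GPS Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmark toolkit for inferring seabird diving behaviour from
    GPS-only trajectories. Provides a seeded multi-state movement simulator
    producing paired GPS and time-depth-recorder records with ground-truth dive
    labels, trajectory preprocessing (trip splitting, 1-s linear interpolation,
    coverage ratios, 2-m dive labelling, downsampling), three window-based
    neural segmentation architectures (fully-connected, fully-convolutional and
    U-shaped 1-D networks) trained with weighted binary cross-entropy and Adam,
    first-passage-time and gamma/von Mises hidden Markov model baselines,
    ROC/AUC and kernel-density dive-map evaluation, and orchestration of
    training, cross-dataset generalization and fine-tuning experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
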