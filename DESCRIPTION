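Package: weevilsense
Title: Acoustic and Video-Based Classification of Mango Pulp Weevil Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize and classify the activity of the mango pulp
    weevil (Sternochetus frigidus) from audio and video recordings. Provides a
    synthetic scene generator with known ground truth (band-limited burst audio
    for mating, pupal movement and adult walking; scripted two-weevil chase and
    mounting videos), fixed-length audio segmentation with RMS normalization and
    signal statistics, a from-first-principles MFCC front-end (Mel filter bank,
    log compression, DCT), SVM activity classification with confusion-matrix
    reports, and a video mating-event segmenter built on Otsu thresholding,
    area-filtered blob detection, distance gating and constant-velocity Kalman
    tracking with overlap-delimited event timestamps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
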