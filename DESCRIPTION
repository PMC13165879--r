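Package: eegverbs
Title: Decoding Spoken Mandarin Verbs from EEG with CSP-SVM and Dual-LSTM Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for six-class decoding of overtly spoken Mandarin action
    verbs (Chi, He, Chuan, Na, Kan, Dai) from eight-channel EEG recorded over
    Broca's and Wernicke's areas. Implements a one-vs-one Common Spatial
    Patterns feature extractor with pairwise radial-basis-function support
    vector machines and majority voting as the baseline decoder, and a
    seven-layer recurrent network (three fully connected layers feeding two
    stacked LSTM layers) trained by seeded mini-batch gradient descent with an
    optional exact line-search learning rate, as the proposed decoder. Includes
    the band-pass/epoching preprocessing front end, 13-coefficient MFCC
    reference features from the time-aligned audio channel, confusion-matrix
    metrics and learning-curve protocols, and a seeded synthetic-EEG generator
    reproducing the study design (30 subjects x 6 verbs x 75 trials at 250 Hz)
    with controllable spatial and temporal class structure so the whole
    pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
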