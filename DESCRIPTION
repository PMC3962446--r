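Package: songsvm
Title: Semi-Automatic Birdsong Syllable Segmentation and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments syllables from continuous birdsong recordings by
    amplitude-envelope thresholding with automatic noise-floor estimation,
    extracts a 532-dimensional acoustic feature vector per syllable
    (spectrum, cepstrum, their temporal derivatives, and summary acoustic
    features), trains linear soft-margin support vector machines from a
    small human-labeled instruction set, classifies large recordings, and
    estimates whole-dataset labeling accuracy from classifier margin scores
    without full manual verification. Includes a synthetic Bengalese-finch
    song generator with exact ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
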