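Package: fbcsp
Title: Filter-Bank Common Spatial Patterns with Principle-Channel Selection
    for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-class motor-imagery EEG classification built on filter-bank
    common spatial patterns (FBCSP) restricted to a data-driven channel
    subset.  The most class-discriminative channel (the "principle channel")
    is chosen by the Fisher ratio of Hjorth-style time-domain parameters;
    a supporting channel set is formed from channels whose class-mean
    correlation with the principle channel exceeds a threshold; one CSP
    filter pair is fitted per filter-bank band on that subset; the two
    bands with the highest mutual information between their log-variance
    features and the class label are kept; a linear maximum-margin
    classifier operates on the resulting 4-dimensional feature vector.
    Includes epoch extraction from continuous recordings, a minimal EDF/EDF+
    reader and writer, repeated stratified cross-validation with nested
    threshold selection, and a seeded generator of synthetic
    event-related-desynchronization sessions with ground truth for
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
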