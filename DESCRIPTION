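Package: proofreadr
Title: Segmentation-Based Connectome Proofreading Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for collaborative proofreading of electron-microscopy
    segmentations. Provides run-length-encoded sparse body volumes with multi-scale
    downsampling and block covers, a versioned block-based label store with a grayscale
    companion (merge, split, commit/branch, body diff), a seeded-watershed split engine
    with bounded computation and connected-component reattachment, workflow annotations
    (body statuses, bookmarks, to-do marks, synapses with directed pre/post links, a
    sequencer table), a lock-based multi-user coordinator, and a synthetic EM-like
    fixture generator. Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
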