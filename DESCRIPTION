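Package: saibr
Title: Spectral Autofluorescence Correction for Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates linear inter-channel models of cellular
    autofluorescence from unlabeled (or red-fluorophore-only) reference
    images and uses them to infer and subtract autofluorescence from a
    primary fluorophore channel, pixel by pixel. Supports two-channel and
    three-channel correction, GFP spillover compensation, batch
    processing, region-of-interest and cross-membrane quantification,
    and a synthetic multi-channel scene generator with stored ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
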