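Package: rtdeinterp
Title: De-Interpolation of Radiotherapy Structure Set Contours
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Thins organ-at-risk and target contours stored in DICOM RT
    Structure Set files by clearing contours on a modular pattern of axial
    CT slices ("de-interpolation"), so that AI- or manually generated
    structures can be re-edited on a sparse subset of slices and then
    re-interpolated in a treatment planning system. Provides keep mode
    (clear every 1-in-n contoured slice) and erase mode (clear all but
    every n-th contoured slice, optionally preserving the first), an
    optional slice range, structure copying, a minimal DICOM reader and
    writer for RTSTRUCT and CT geometry, synthetic phantom generators for
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
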