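Package: anatscaffold
Title: Annotated Cubic Hermite Scaffolds for Anatomical Data Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, fitting and using annotated cubic Hermite
    finite-element scaffolds as anatomical common coordinate frameworks.
    Generates species-specific organ and whole-body scaffolds (colon, atria,
    body) from anatomical parameters, fits scaffold coordinate fields to
    segmented specimen contours by iterated closest-point projection and
    regularized linear least squares, and embeds point data (e.g., neurons)
    as material coordinates so they can be transferred onto a generic
    scaffold for cross-specimen and cross-species comparison. Includes
    readers and writers for an annotated segmentation XML dialect, a
    versioned native mesh format, VTK export, and a synthetic-specimen
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
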