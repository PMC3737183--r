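Package: wingtrich
Title: Trichome Detection and Wing Morphometry for Insect Wing Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable morphometric analysis of insect wing photomicrographs.
    Detects the dark base of each wing trichome by prominence-based ("noise
    tolerance") local-maxima finding on the inverted image, measures trichome
    counts and densities in user-defined square or polygon regions, segments
    vein and intervein territory with a trainable per-pixel random-forest
    classifier followed by particle analysis, partitions the blade into
    per-trichome spacing cells with a seeded watershed, and renders intervein
    area and trichome spacing heat maps. Includes a synthetic wing generator
    with full ground truth (trichome coordinates, vein/intervein/background
    masks, per-compartment density rates) emulating the two classes of
    detection failure seen in real transmitted-light micrographs, plus
    detection-accuracy evaluation utilities and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    jpeg,
    jsonlite,
    randomForest,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
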