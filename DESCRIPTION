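Package: mcdetect
Title: Microcalcification Cluster Detection in Mammograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided detection of microcalcification clusters in
    grayscale mammograms. Individual microcalcifications are enhanced with a
    multi-structuring-element morphological top-hat transform (a bank of
    rotated line elements), refined by a multilevel symlet-2 wavelet
    decomposition in which selected subbands are zeroed to suppress
    gland- and vessel-like curvilinear structures, segmented by thresholding
    and connected-component labeling, and grouped into clusters with an
    overlapping-block rule (four or more components within a 10 x 10 mm
    block). Includes a seeded synthetic phantom generator with ground truth
    and true-positive-rate / false-positives-per-image scoring, so the full
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
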