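Package: tensionmap
Title: Image-Based Tension Mapping of the Adherent Cell Cytoskeleton
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts fluorescence images of an adherent cell (actin,
    focal-adhesion marker, nucleus) into a pre-stressed mechanical node
    network, calibrates its contractility against focal-adhesion forces by
    inverse mechanics, and measures intracellular tensions and per-stress-fiber
    tensions directly on the actin image via cross-linear tension densities.
    Includes a synthetic-cell image generator with ground truth so the whole
    pipeline is testable without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    data.table,
    igraph,
    jsonlite,
    pracma,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
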