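Package: emtquant
Title: Quantification of EMT-Like Phenotypes in Live-Cell Imaging Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image- and table-based quantification of epithelial-to-mesenchymal
    transition (EMT)-like phenotypes in cultured cells: variance-based
    segmentation of phase-contrast micrographs and confluency time series,
    cell-cluster size distributions and small-cluster band frequencies,
    collective motility estimation by particle image velocimetry (PIV),
    net-displacement statistics of single-cell trajectories, spheroid
    compactness via the normalized perimeter, solitary-cluster invasion
    fractions in 3D matrix assays, pixel-wise Pearson co-localization of
    fluorescence channels, and relative gene expression by the 2^-ddCt
    method. Ships a seeded synthetic-scene generator that emits ground truth
    for every stage, so the whole pipeline is testable without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    tiff,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
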