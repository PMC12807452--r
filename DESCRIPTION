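Package: spotcoloc
Title: Colocalization and Randomization-Null Analysis of Punctate
    Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the spatial association of two punctate fluorescence
    channels in 2D microscopy images: connected-component particle extraction
    with physical-unit areas and densities, binary overlap colocalization,
    compartment classification against organelle masks, edge-to-edge
    nearest-distance statistics, cumulative dilation ("ring") localization
    preference profiles, and a particle-preserving spatial randomization null
    that redraws particles as equal-area circles at uniform positions inside
    the cell perimeter. Includes a synthetic-scene generator (polygonal cells,
    organelle masks, coupled bivariate particle fields with known ground
    truth) so the full pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    pracma,
    igraph,
    EBImage,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
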