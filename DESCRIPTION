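Package: dixpol
Title: Reconstruction and Analysis of Helical DIX-Domain Polymers from
    Crystal Symmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing head-to-tail helical homopolymers of
    DIX domains (and similar ubiquitin-like folds) from crystallographic
    asymmetric units. Expands deposited coordinates with unit-cell and
    space-group operators, detects beta-bridge head-to-tail interfaces,
    assembles protofilaments, classifies single- versus double-helical
    architecture, estimates screw parameters (rise, twist, pitch,
    handedness) from consecutive subunits, and quantifies interfaces with
    Shrake-Rupley accessible surface areas and typed contact inventories
    (hydrogen bonds, salt bridges, hydrophobic and water-mediated
    contacts). Includes a synthetic-assembly generator with exact ground
    truth so every stage of the pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
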