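Package: wspdeposit
Title: Spray Deposit Analysis from Water-Sensitive Paper Cards
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies pesticide spray deposition from scanned
    water-sensitive paper (WSP) cards. Segments droplet stains from
    grayscale card scans, converts stain sizes to droplet diameters and
    volumes under either a constant power-law spread factor or a
    diameter-binned variable spread factor, and summarises per-card
    coverage, droplet density and liquid deposition. Deposition is
    converted to active-ingredient residue from the tank-mix
    concentration, and WSP-derived residues can be calibrated against
    analytically measured leaf residues through an empirical correction
    factor. Includes a synthetic-card generator for validation
    experiments on computer-generated circular stains (spread-factor
    comparison and the touching-droplet merging artefact) and
    nested-scale field summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Software, Preprocessing, Segmentation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
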