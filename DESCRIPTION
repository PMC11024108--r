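Package: clasp
Title: Cross-Link Assisted Spatial Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers sub-organelle protein localizations and membrane-protein
    topologies from proteome-wide cross-linking mass-spectrometry (XL-MS)
    data. Known localization markers are propagated through the cross-link
    network under a compartment model of the organelle (aqueous compartments
    separated by membranes), with geometric plausibility checks based on the
    cross-linker labeling radius and a synthetic-organelle simulator for
    validation of every inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, NetworkInference, Software
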