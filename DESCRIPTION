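Package: guvquant
Title: Quantification of Lectin Binding to Giant Unilamellar Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for lectin-membrane binding assays imaged by
    confocal microscopy. Detects giant unilamellar vesicles (GUVs) in
    equatorial sections by a circular Hough transform on the membrane-marker
    channel, extracts angular rim intensity profiles, computes the
    rim-versus-solution binding-efficiency contrast, segments the rim into
    liquid-ordered and liquid-disordered arcs from an ld-marker staining
    pattern, quantifies per-phase binding and rim segregation of two lectins,
    measures apical-to-basolateral intensity ratios of polarized epithelial
    cells in z-stacks, and aggregates per-GUV statistics with nonparametric
    pairwise testing. Includes a forward simulator producing multi-channel
    images with exported ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
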