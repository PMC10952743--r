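Package: srsphasor
Title: Spectral Phasor Unmixing of Hyperspectral Stimulated Raman Scattering Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hyperspectral stimulated Raman scattering
    (SRS) microscopy stacks with spectral phasor analysis. Provides readers
    and writers for multi-page TIFF stacks bound to a wavenumber axis,
    per-pixel first-harmonic phasor transformation of (possibly multi-window)
    stacks, phasor-space segmentation by polygon gating or seeded k-means
    with back-mapping to label images, per-segment average spectra, a
    parametric reference-spectrum library for bioorthogonal Raman tags
    (metallacarborane B-H, bis-alkyne, deuterated fatty acid, EdU), and
    relative-intensity-to-EdU (RIE) quantification. A synthetic-scene
    generator emulates single-plex and triplex labelling experiments with
    pixel-level ground truth for validating the segmentation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    png,
    jsonlite,
    yaml,
    pracma,
    clue,
    withr,
    tools,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
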