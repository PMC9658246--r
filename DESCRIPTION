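Package: octseg
Title: Segmentation of Outer and Inner Fingerprints from Volumetric OCT Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Digital signal-processing chain for locating and extracting two
    stacked anatomical surfaces from volumetric optical coherence tomography
    (OCT) fingertip scans: the epidermal skin surface (the "outer
    fingerprint") and the dermal-epidermal junction (the "inner
    fingerprint"). Provides an adaptive sparse 1D edge-detection filter,
    intensity roll-off compensation, a multi-resolution volume pyramid with
    multiplicative contrast enhancement, coarse-to-fine surface detection
    with per-scan-line kernel selection, intensity-based fingertip masking,
    ridge-top surface envelopes, envelope-based volume flattening, and
    conversion of the segmented 3D surfaces to conventional 2D grayscale
    fingerprint images. A synthetic OCT fingertip phantom generator with
    exact ground truth makes the entire chain testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
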