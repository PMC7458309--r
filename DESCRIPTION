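Package: arteriowall
Title: Quantitative Wall Analysis of Arterial Cross-Sections from En-Face
    Optical Tomography Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of transverse artery sections
    imaged with full-field optical coherence tomography (FF-OCT). Provides a
    synthetic phantom generator for temporal-artery-biopsy-like sections with
    known ground truth, z-projection of image stacks, radial contrast-profile
    segmentation of the tunica intima, media and adventitia with
    intima-to-media (I/M) ratio classification, Gabor filter-bank fiber
    orientation mapping, a 180-degree rotational-symmetry score for wall
    architecture, and the accompanying rank-sum and correlation statistics,
    orchestrated by a reproducible end-to-end study runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
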