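Package: mwbreast
Title: Simulation and Analysis of Transmission-Based Microwave Breast Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates bilateral, four-view breast scans for a planar
    ultra-wideband microwave transmission system and reproduces the full
    analysis chain used to study contralateral permittivity asymmetry:
    synthetic breast phantoms with mammographic density categories and
    optional tumor inclusions, straight-ray forward simulation of per-path
    transmission spectra, time-of-arrival permittivity reconstruction via an
    inverse chirp Z-transform, k-means and threshold-based tissue
    segmentation, and cohort-level asymmetry statistics (contralateral
    ratios, ANOVA, t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    withr,
    car,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
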