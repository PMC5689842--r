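Package: cryodose
Title: Skin-Surface Dosimetry with Radiochromic Cryogel Bolus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for measuring skin-surface dose in external-beam
    radiotherapy with translucent radiochromic poly(vinyl alcohol) cryogel
    bolus read out optically. Converts pre/post-irradiation 16-bit grayscale
    images into Beer-Lambert linear absorption-coefficient maps and film scans
    into net-optical-density maps, fits signal-to-dose calibrations, registers
    bolus and film dose maps, derives and applies the bolus-to-skin correction
    factor from oblique-incidence irradiations, predicts the normal-incidence
    bolus-average-to-surface ratio by percent-depth-dose integration, and
    validates agreement with a from-scratch 2D gamma index (3%/3 mm, 10%
    threshold). Includes a deterministic synthetic-data generator that emulates
    the full measurement chain so every stage is testable without physical
    irradiations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    generics,
    jsonlite,
    tiff,
    pracma,
    sandwich,
    withr,
    EBImage,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
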