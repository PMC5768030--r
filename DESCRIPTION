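Package: dwmetrics
Title: Water-Equivalent Diameter Patient Size Metrics and Dose Indices for CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-slice water-equivalent diameter Dw(z) from CT image
    series (with CT-table attenuation correction), the mid-scan metric Dw_c and
    the scan-average metric Dw_ave, and size-specific dose estimates (SSDE)
    from CTDIvol using 32-cm body-phantom conversion factors. Includes a
    minimum-tube-current (Imin) thresholding simulation for automatic tube
    current modulation (ATCM), descriptive cohort statistics comparing how
    well dose indices track each size metric, a minimal DICOM CT reader and
    writer, and a synthetic-data module (analytic phantoms, anatomy-shaped
    Dw(z) profiles, a noise-constant ATCM emulator, and a seeded patient
    cohort generator) for end-to-end validation.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
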