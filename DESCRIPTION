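Package: mammoqc
Title: Automated Image Quality Scoring of the ACR Digital Mammography Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quality-control analysis of ACR Digital Mammography
    accreditation phantom (Model 086) images. Locates the wax insert by
    morphological processing, partitions it into 18 per-object regions of
    interest, detects fibers, microcalcification speck groups and masses by
    normalized cross-correlation template matching with per-object
    supplementary validators (2D Gaussian mass fit, speck Euclidean-distance
    check, fiber blob-orientation check), applies the count-until-zero
    scoring rule, and evaluates pass/fail against the RANZCR and ACR
    criteria. Includes a minimal DICOM reader/writer, a synthetic phantom
    image simulator with known ground truth for end-to-end testing, and
    inter-rater agreement statistics (ICC, Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
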