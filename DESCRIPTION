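Package: cvdstair
Title: Adaptive Confusion-Line Staircase Engine for Pediatric Colour Vision Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale engine for gamified colour-vision-deficiency (CVD)
    screening on calibrated tablet displays. Provides MacLeod-Boynton cone
    chromaticity math with device RGB/LMS calibration profiles, generation of
    protan, deutan and tritan confusion-line targets masked by luminance and
    binary tritan noise, a three-axis adaptive staircase session controller,
    model-free (local-linear kernel) psychometric function fitting with
    threshold extraction, a tritan:red-green threshold-ratio classifier with
    criterion derivation and diagnostic accuracy metrics, and parametric
    simulated observers (normal trichromats, anomalous trichromats,
    dichromats) for end-to-end validation without human data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
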