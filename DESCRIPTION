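Package: agrowth
Title: LMS-Based Growth Assessment for Pediatric Achondroplasia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated growth assessment for children with achondroplasia
    using the lambda-mu-sigma (LMS) method. Computes sex- and age-specific
    z-scores and percentiles for nine anthropometric parameters (height,
    weight, BMI, head circumference, sitting height, leg length, arm span,
    relative sitting height, foot length) from LMS reference bundles, with
    linear age interpolation of coefficients, inverse centile computation,
    batch processing of patient measurement files, a reference-bundle
    schema validator, and a synthetic reference/cohort generator with
    known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
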