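Package: sfhchart
Title: Symphysis-Fundal Height Growth Charts and Diagnostic Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building, tabulating and validating symphysis-fundal
    height (SFH) reference charts with linear expected values and linear
    lower/upper bounds. Classifies pregnancies into predicted small-,
    appropriate- and large-for-gestational-age (SGA/AGA/LGA) groups from
    longitudinal SFH measurements, validates predictions against a
    gold-standard newborn size classification (sensitivity, specificity,
    predictive values and accuracy with Wilson score intervals), compares
    two charts on paired subjects with McNemar's test, and simulates
    longitudinal antenatal cohorts so the whole pipeline can be exercised
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
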