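Package: cribwatch
Title: Non-Intrusive Infant Monitoring from Camera Pulse Signals and Indoor Air Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for contactless monitoring of sleeping infants. Estimates
    heart rate from webcam-derived RGB region means by remote
    photoplethysmography (detrending, fixed-point independent component
    analysis, band-limited spectral peak detection), checks a multivariate
    indoor air-quality stream (temperature, humidity, CO, CO2, smoke) against
    the indoor maximum-concentration standard, learns robust personalized
    per-context acceptable ranges (median +/- k MAD with statutory safety
    caps), and classifies each monitoring instant into a four-level severity
    scale (Normal/Warning/Alert/Emergency) that is compared against a naive
    binary threshold baseline. Includes seeded synthetic generators for
    pulse-bearing RGB traces, rendered frames, and diurnal sensor streams with
    injected excursions, providing ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
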