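Package: eggclock
Title: Thermal Development and Morphological Age Estimation for Blow Fly Eggs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the age of Calliphora vicina (Diptera: Calliphoridae)
    eggs from embryonic morphological landmarks, for forensic entomology
    workflows where egg age bounds a minimum post-mortem interval (PMI_min).
    Implements an accumulated-degree-hour (ADH) thermal development model with
    rate summation over arbitrary temperature histories (lower developmental
    threshold 1 degree C), a staging calibration of 15 externally visualisable
    embryonic landmarks scored across eleven 10 percent developmental intervals
    at two calibrated temperatures (7.3 and 25 degrees C), a likelihood-based
    interval estimator with preservation-dependent observability masking (live
    scoring, hot-water-killed + ethanol, or direct ethanol), and a seeded
    synthetic cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
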