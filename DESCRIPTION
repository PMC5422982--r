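Package: ineqhc
Title: Income-Related Inequality and Horizontal Inequity in Health Care Utilization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Measures income-related inequality in binary health care
    utilization with the standard and Erreygers-corrected concentration
    indices against weighted fractional income ranks, estimates horizontal
    inequity by linear-model indirect standardization, decomposes the
    Erreygers index into per-covariate contributions, and attaches
    percentile-bootstrap confidence intervals with household-level
    resampling. Includes household equivalence scales for income per
    equivalent adult and a synthetic household-survey generator with
    planted inequality structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
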