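Package: mrpipe
Title: Two-Sample Mendelian Randomization with Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Summary-statistics Mendelian randomization toolkit: instrument
    selection (genome-wide significance, LD clumping, minor-allele-frequency
    and palindrome filters, F-statistics), exposure-outcome allele
    harmonization, causal estimators (Wald ratio, inverse-variance weighted,
    MR-Egger, weighted median), a sensitivity battery (Cochran's Q, Egger
    intercept, MR-PRESSO outlier detection, leave-one-out), multivariable MR,
    and two-step mediation decomposition, together with a fully specified
    synthetic GWAS summary-statistics generator so every stage is testable
    without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
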