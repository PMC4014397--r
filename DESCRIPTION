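Package: dynsup
Title: Linear Superposition Analysis of Promoter Activity Dynamics in
    Combined Growth Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bacterial promoter activity dynamics measured
    by fluorescent reporters across combinatorial growth conditions. Converts
    plate-reader optical-density and GFP time series into promoter-activity
    and growth-rate curves on a shared generation axis, decomposes per-promoter
    dynamics across conditions into principal component curves, fits
    combined-condition dynamics as weighted averages (linear superposition) of
    single-condition dynamics under unconstrained error-in-variables,
    simplex-constrained and multiplicative models, and predicts mixture
    weights for triplet and quadruplet condition cocktails from pairwise
    measurements. Includes a synthetic plate-experiment generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
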