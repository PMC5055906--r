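Package: ast120di
Title: Drug-Interaction Risk Prediction for the Oral Adsorbent AST-120
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the risk of pharmacokinetic interaction between the oral
    spherical-carbon adsorbent AST-120 and co-administered drugs from their in
    vitro dissolution and in vivo oral-absorption behaviour. Fits the extended
    Noyes-Whitney dissolution model and one- or two-compartment oral absorption
    models with lag to measured curves, evaluates theoretical dissolution (Rd)
    and absorption (Ra) rates at candidate dosing intervals, optimizes
    equivalence-prediction thresholds (Rdth, Rath) against interaction-study
    outcomes by exact breakpoint search, and classifies drugs into four
    interaction-risk groups per dosing interval.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
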