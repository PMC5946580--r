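Package: sadige
Title: Structured Antedependence Mixed Models with Indirect Genetic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal quantitative-genetic analysis of group-housed
    animals using structured antedependence (SAD) covariance models that
    include correlated direct and indirect (social) genetic effects.
    Provides SAD covariance construction from polynomial parameter
    functions, pedigree relationship matrices and their sparse inverses,
    residual-free REML estimation via sparse mixed-model equations, BLUP
    prediction of direct and indirect breeding values, heritability and
    total-heritable-variance summaries with sampling-based standard
    errors, a closed-nucleus selection simulator, and a synthetic
    longitudinal data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
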