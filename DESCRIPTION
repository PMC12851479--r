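Package: cmrlmm
Title: Compositional Multivariate-Response Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits linear mixed models with a compositional response, such as a
    24-hour time-use composition of sleep, sedentary behaviour and physical
    activity. The D-part composition is expressed as D-1 orthonormal log-ratio
    (olr/ilr) coordinates built from a sequential binary partition or pivot
    scheme, and all coordinates are modelled jointly with correlated random
    intercepts (unstructured between-subject covariance G) and correlated
    residuals (unstructured within-occasion covariance E), estimated by REML or
    ML. Provides joint multivariate F and Wald tests on fixed-effect blocks,
    likelihood-ratio tests between nested covariance structures,
    back-transformation of coefficients and predictions into the simplex,
    log-ratio differences between conditions, subject-level cases bootstrap
    percentile intervals, comparator fits (unrelated-outcomes, univariate
    per-coordinate, raw-minutes), and a generator of synthetic multilevel
    compositional data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
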