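Package: cssd
Title: Bayesian Sample Size Determination with Commensurate Predictive Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian sample size determination for two-group experiments that
    leverage pre-experimental information from multiple sources. Historical
    summaries are combined into a robust collective normal prior through
    commensurate predictive priors with two-component Gamma mixture priors on
    the predictive precisions, and sample sizes are solved under the average
    coverage (ACC), average length (ALC), and average posterior variance (APVC)
    criteria, for both known and unknown sampling variance (the latter via an
    inverse-gamma prior induced by a chi-square link to the collective prior
    variance). Includes comparator borrowing strategies, scenario sweeps,
    Monte-Carlo verification of the average posterior properties, and
    configuration-file driven workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
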