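Package: lifeconv
Title: Exact Convolution Tests for Small-Cohort Lifespan Trials and
    Hill Dose-Response Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Statistical toolkit for rodent longevity trials that compare
    small treated cohorts against a large reference cohort, built around an
    exact test for the mean lifespan: the null distribution of the mean of n
    control animals is obtained by n-fold convolution of the empirical
    lifespan probability mass function, and a directional p-value is read off
    the exact tail. Includes Kaplan-Meier and log-rank survival summaries,
    percent-of-control cohort tables, a Gompertz-mortality simulator for
    generating realistic synthetic trials, and Hill-equation dose-response
    fitting with extra sum-of-squares F-test curve comparison for
    electrophysiological concentration-response data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
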