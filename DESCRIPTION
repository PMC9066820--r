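Package: icsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case/non-case (disproportionality) analysis of
    individual case safety reports (ICSRs). Provides a relational ICSR data
    model with MedDRA-style (PT/HLT/SOC) and ATC terminologies and query
    expansion, the Bayesian Information Component (IC) with gamma-quantile
    and asymptotic credible intervals and the IC025 > 0 signal rule,
    comparator-restricted (comparative) disproportionality, descriptive
    summaries of report characteristics (demographics, time to onset,
    monthly dose, seriousness, outcomes, co-reported terms), and a
    configurable simulator of spontaneous-report stores with injected
    drug-event associations for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
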