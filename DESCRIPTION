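Package: lcscreen
Title: Markov Cohort Cost-Effectiveness Analysis of Lung Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic toolkit for evaluating low-dose CT lung cancer
    screening programmes in high-risk smokers and ex-smokers. Implements an
    annual-cycle Markov cohort model of lung cancer natural history stratified
    by histology and TNM stage, screening scenarios with stage shift between
    screen-detected and clinically detected disease, discounted cost and QALY
    accumulation from the healthcare perspective, incremental
    cost-effectiveness analysis with strict and extended dominance on the
    efficiency frontier, budget impact streams, and probabilistic sensitivity
    analysis producing cost-effectiveness acceptability curves (CEAC) and the
    acceptability frontier (CEAF). A synthetic parameter generator emulates
    the structure of registry- and trial-derived model inputs so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
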