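Package: padscreen
Title: Cost-Effectiveness of Ankle-Brachial-Index Screening for Peripheral Arterial Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model of one-time ankle-brachial-index (ABI)
    screening for peripheral arterial disease (PAD) followed by antiplatelet
    prevention (low dose aspirin or clopidogrel), compared with no screening.
    Couples a screening decision tree to an annual-cycle lifetime Markov cohort
    model over eight cardiovascular health states, accumulates discounted and
    undiscounted costs, life years and QALYs, and quantifies decision
    uncertainty through probabilistic sensitivity analysis (Monte Carlo over
    Beta, Gamma and Beta-PERT parameter distributions), cost-effectiveness
    acceptability curves, cost-effectiveness plane summaries, and one-way and
    two-way deterministic sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
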