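Package: pmbcea
Title: Decision-Analytic Cost-Effectiveness Modelling of Diagnostic
    Strategies for Postmenopausal Bleeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating diagnostic strategies for endometrial
    cancer in women presenting with postmenopausal bleeding. Implements
    declarative decision trees over imperfect diagnostic tests (transvaginal
    ultrasound, pipelle biopsy, hysteroscopy, molecular testing on
    cervicovaginal and endometrial samples), a 35-year annual-cycle Markov
    cohort model of endometrial cancer natural history with FIGO stage
    progression, quality-adjusted life-year and cost accounting with
    discounting, incremental cost-effectiveness ratios, and deterministic
    and probabilistic sensitivity analyses (tornado tables, beta/gamma
    parameter draws, cost-effectiveness acceptability curves, test-cost
    sweeps). A microsimulation engine provides an independent cross-check
    of the cohort engine, and a scenario generator supplies degenerate
    fixtures with closed-form outcomes for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
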