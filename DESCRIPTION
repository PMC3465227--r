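Package: renalcea
Title: Cost-Effectiveness Modelling of Dialysis Referral Timing After
    Kidney Graft Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Markov cohort state-transition model for the
    cost-effectiveness of timely versus late dialysis referral after
    kidney transplant failure. Simulates a closed cohort over six renal
    replacement therapy states with age-dependent mortality, half-cycle
    corrected discounted costs and quality-adjusted life years, and
    computes incremental cost-effectiveness ratios, one-way (tornado)
    and late-referral-proportion sensitivity analyses, probabilistic
    sensitivity analysis with moment-matched beta, normal, log-normal
    and uniform distributions, cost-effectiveness acceptability curves
    and the cost-effectiveness plane with its normal-theory confidence
    ellipse. Includes synthetic generators for the model inputs that are
    not published (mortality schedule, non-transplant transition
    structure, first-year cost component breakdowns) calibrated to the
    published parameter totals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
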