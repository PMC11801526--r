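Package: ptsdcea
Title: Markov Cohort Cost-Effectiveness Analysis of PTSD Treatments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-state Markov cohort model (clinically improved, not
    improved, dead) for evaluating the cost-effectiveness of posttraumatic
    stress disorder treatments over a five-year horizon of three-month
    cycles. Implements rate-to-probability conversion, stepwise QALY and
    cost discounting, incremental cost-effectiveness analysis with
    dominance and net-monetary-benefit reporting, one-way tornado
    sensitivity analysis, probabilistic sensitivity analysis with
    moment-matched beta, gamma and triangular samplers and
    cost-effectiveness acceptability curves, plus two independent
    verification oracles (matrix-expectation and individual-level
    microsimulation) and a synthetic three-arm trial generator.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
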