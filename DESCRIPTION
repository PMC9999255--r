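Package: retscreen
Title: Cost-Effectiveness Modelling of Diabetic Retinopathy Telemedicine
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model comparing
    artificial-intelligence grading with manual expert grading in
    community-based diabetic retinopathy telemedicine screening.
    Simulates a cohort of people with diabetes over 30 annual cycles
    through non-sight-threatening retinopathy, sight-threatening
    retinopathy, macular oedema, blindness and death, and computes
    lifetime discounted costs, quality-adjusted life years and years
    without blindness from a societal perspective.  Provides incremental
    cost-effectiveness and cost-utility ratios with WHO
    willingness-to-pay classification, one-way deterministic sensitivity
    analysis (tornado tables and a referral-compliance threshold scan),
    probabilistic sensitivity analysis with beta/gamma/log-normal
    parameter distributions and cost-effectiveness acceptability curves,
    a synthetic scenario generator, and an individual-level
    microsimulation used as an independent oracle for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
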