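Package: pbtcea
Title: Markov Cohort Cost-Effectiveness Analysis of Proton Versus Photon
    Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A 3-state Markov cohort model for the cost-effectiveness of
    intensity-modulated proton therapy compared with intensity-modulated
    photon radiotherapy in paranasal sinus and nasal cavity cancer.
    Builds per-cycle transition matrices combining disease transitions
    with life-table background mortality, accrues discounted costs and
    quality-adjusted life years, and computes incremental
    cost-effectiveness ratios and net monetary benefit. Includes
    probabilistic sensitivity analysis with beta and truncated-normal
    parameter distributions, tornado diagrams, one-way threshold
    searches by bisection, age-stratified analyses, a paired Monte Carlo
    strategy-selection simulation, and a patient-level microsimulation
    that serves as a brute-force cross-check of the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
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
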