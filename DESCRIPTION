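Package: lccusum
Title: Learning Curve CUSUM Competency Monitoring for Simulation-Based
    Surgical Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequential competency monitoring with the learning curve
    cumulative summation test (LC-CUSUM) for pass/fail simulation
    training, as used in mastery-learning curricula for dynamic hip
    screw (DHS) surgery. Builds Bernoulli log-likelihood-ratio chart
    designs (continuous and integer-scored multi-level program
    variants), runs charts over procedure outcome streams with a
    holding barrier, computes exact finite-horizon operating
    characteristics by dynamic programming alongside Monte Carlo
    estimates, calibrates the signal limit, classifies individual
    procedures from metrics such as tip-apex distance with a
    configurable conjunctive rule set, generates synthetic learner
    cohorts with exponential-decay learning curves and linked career
    outcomes, and analyses the resulting pass/fail-by-career 2x2 table
    (predictive values with Wilson intervals, Fisher's exact and
    chi-square tests, group summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
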