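Package: cogstage
Title: Actuarial Cognitive Staging and Validity Analyses for Longitudinal
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for operationalising the research category "cognitively
    unimpaired - declining" (CU-D) in longitudinal ageing cohorts. Implements
    robust regression-based internal norms (demographically adjusted
    z-scores and standard-score composites), a two-tier flagging algorithm
    with a deterministic actuarial stand-in for consensus status assignment
    (CU-S, CU-D, MCI, dementia), progression and reversion outcome
    construction, the accompanying statistical machinery (Cliff's delta,
    Cramer's V, exact binomial intervals, Benjamini-Hochberg FDR,
    two-proportion power, change-score ANCOVA, adjusted logistic progression
    models), and amyloid/tau PET biomarker quantities (Logan graphical DVR,
    PiB positivity and chronicity, data-derived tau SUVR thresholds). A
    calibrated synthetic-cohort generator with latent Markov state dynamics
    makes every stage testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
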