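Package: ucmayo
Title: Linked Longitudinal Proportional-Odds Models of the Mayo Clinical Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and estimation machinery for a linked longitudinal
    model of the Mayo Clinical Score (MCS) and its subscores in
    placebo/standard-of-care treated patients with moderate to severe
    ulcerative colitis.  The rectal bleeding plus stool frequency (RB+SF),
    endoscopy (ENDO) and physician's global assessment (PGA) subscores are
    each described by a proportional-odds model with a subject-level random
    effect; the RB+SF subscore drives the ENDO and dropout models as a
    time-varying covariate and the modified MCS drives the PGA model.
    Includes a synthetic five-trial cohort generator, maximum-likelihood
    estimation with adaptive Gauss-Hermite or Laplace marginalization,
    score-driven dropout fitting, stepwise covariate modeling, nonparametric
    bootstrap, and categorical/continuous visual predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    ggplot2,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
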