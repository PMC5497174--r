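Package: demproj
Title: Dementia Incidence Trends and Multi-State Prevalence Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating calendar trends in dementia incidence from
    biennial ageing-panel data and projecting dementia prevalence with a
    discrete-time multi-state (Markov) cohort model. Includes a synthetic
    cohort generator emulating a six-wave panel of adults aged 50+ with
    latent cognitive trajectories and informative dropout; an operational
    dementia case definition based on cognitive test scores, activities of
    daily living and informant questionnaires; naive, competing-risks and
    joint-model (shared random effects) estimators of the incidence trend
    that correct for selective attrition; calibration of age-sex-calendar
    specific one-year transition probabilities across eight health states
    plus cause-specific death; an annual cohort projection engine with entry
    cohorts, life expectancy and disability-free life expectancy; and Monte
    Carlo probabilistic sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    lme4,
    MASS,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
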