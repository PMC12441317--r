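Package: aalearn
Title: Rescorla-Wagner Modelling of Continuous Approach-Avoidance Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of an intergroup
    approach-avoidance learning task with a continuous distance response.
    Provides the task designs (conflicting 80/20, random 50/50 and
    non-social reward schedules), a synthetic-cohort generator with
    biased starting values, reinforcement-driven drift, response noise
    and invalid trials, six Rescorla-Wagner model variants with
    valence- and group-specific learning rates fitted per participant
    by bound-constrained multi-start SSE minimisation, BIC/R-squared
    model comparison, Welch parameter contrasts, a paired-t power
    calculator, and parameter- and model-recovery studies validating
    the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
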