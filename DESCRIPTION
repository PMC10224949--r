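Package: outlierlift
Title: Outlier-Paradigm Object-Lifting Task: Simulation, Categorical-Encoding
    Metric, and Directional Bayes-Factor Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the outlier paradigm in sensorimotor category learning,
    in which participants anticipate the weights of a constant-density object
    family and an interleaved denser outlier by stretching a virtual spring.
    Provides the twelve task conditions with constrained block-randomized trial
    schedules, the analytic spring-mass-damper trial physics with the task's
    score and time-penalty functions, a generative model of synthetic
    participants with a latent categorical-encoding strength, robust
    scaled-MAD trial and participant exclusion, the per-participant strength
    of categorical encoding metric with its family-regression analyses,
    a directional Bayes-factor engine (Student-t summary-statistic likelihood,
    point null, half-normal alternative with a quantile-based scale rule,
    Welch-Satterthwaite degrees of freedom), and a simulation-based Bayesian
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
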