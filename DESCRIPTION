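Package: banditrt
Title: Simulation and Model-Based Analysis of Four-Armed Bandit Tasks
    Under Time Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying exploration-exploitation behavior in
    four-armed bandit tasks with a within-subject time-pressure manipulation.
    Simulates the task (crossed payoff and time conditions, reward shifting,
    response deadlines, performance bonus), tracks per-option reward beliefs
    with a Bayesian mean tracker (a Kalman filter for static means), fits a
    hierarchical softmax choice model with an uncertainty-directed exploration
    bonus and choice stickiness, fits Linear Ballistic Accumulator models to
    joint choice and response-time data by differential-evolution MCMC, and
    links belief-derived predictors (relative reward, relative uncertainty,
    total uncertainty) to response times and drift rates through Bayesian
    hierarchical regressions. Includes a synthetic-cohort generator with known
    ground truth for parameter-recovery studies, descriptive behavioral
    statistics (learning curves, choice entropy, repeat choices,
    chance-normalized choice proportions), tidy and glance methods, and
    ggplot2 visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
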