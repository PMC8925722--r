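Package: matchpennies
Title: Behavioral Models, Opponent Algorithms, and Pupillometry for
    Competitive Choice Tasks in Head-Fixed Mice
Version: 0.1.0
Authors@R:
    person("Penny", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying iterative matching-pennies play and
    two-armed bandit behavior in head-fixed mice. Implements the
    history-mining computer opponent (conditional-probability prediction
    with exact binomial tests and counter choices), trial timing with
    truncated-exponential intertrial intervals, five trial-by-trial
    decision models (win-stay-lose-switch and Q-learning variants with
    forgetting and choice kernels), constrained maximum-likelihood
    fitting with BIC model comparison, behavioral statistics
    (three-choice entropy, running-entropy session truncation,
    psychometric curves, reward-rate parameter sweeps), and a
    trial-aligned pupillometry pipeline (4-Hz lowpass, MAD outlier
    masking, moving-window z-scoring, baseline-subtracted responses, and
    per-bin multiple linear regression with significance-fraction
    summaries). A synthetic-data module generates behavioral sessions
    and pupil traces with known ground truth so every stage is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
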