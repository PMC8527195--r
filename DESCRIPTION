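Package: socialbandit
Title: Q-Learning Models of Advice and Observation in a Two-Armed Bandit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, likelihood-based fitting and behavioural analysis of a
    social two-armed bandit ("fishing") task in which a single accurate social
    cue (advice or an observed choice) arrives after the fourth trial of a
    15-trial block. Implements a delta-rule Q-learning agent with a softmax
    choice rule extended by one-time social boosts: a value boost that lifts
    the cued option toward a ceiling, and a precision boost that replaces the
    softmax inverse temperature for the remainder of the block. Provides
    per-participant constrained maximum-likelihood estimation (multi-start
    L-BFGS-B) with exploiter/explorer classification of the post-cue precision,
    simulation experiments over boost parameters and mixture populations,
    preregistered-style behavioural measures (immediate cue following,
    long-term performance, convergence, U-value choice stochasticity, response
    time filtering, bonus payments) with bootstrap cohort summaries, and a
    seeded synthetic cohort generator with a paranoia covariate for closed-loop
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
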