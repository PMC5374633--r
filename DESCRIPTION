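Package: diveHMM
Title: Hidden Markov Models for Classifying Cetacean Dives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies whale dives into latent behavioural states with
    multivariate hidden Markov models. Dives are segmented from depth records
    at a 20 m threshold and summarised by duration, maximum depth and the
    number of echolocation buzzes; the three variables are modelled with
    state-dependent Gamma, Gamma and Poisson distributions under
    contemporaneous conditional independence. Supports discrete random
    effects on the transition matrix (a whale-level finite mixture of
    transition matrices), multi-start numerical maximum likelihood, AIC/BIC
    selection over a model catalogue, Viterbi decoding, empirical transition
    and bout summaries, per-whale time budgets, tag-duration regressions with
    noncentral-F power computations, and a synthetic study generator for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
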