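# diveHMM

Hidden Markov models for classifying whale dives into behavioural states.

Deep-diving toothed whales are usually described with a crude dichotomy —
deep foraging dives versus shallow non-foraging dives. Dive records from
archival tags (DTAGs) carry much more structure than that: dives cluster in
bouts, intermediate dive types exist, and foraging effort (echolocation
buzzes, a proxy for prey-capture attempts) varies strongly between dive
types. `diveHMM` is for biologists analysing such records: it segments a
depth time series into dives, summarises each dive by three variables, and
classifies dives into latent behavioural states with a multivariate hidden
Markov model, following the analysis design used for short-finned pilot
whales tagged off Cape Hatteras.

## The model

Each dive *t* of whale *w* contributes an observation triple
*x<sub>t</sub>* = (duration in minutes, maximum depth in meters, buzz
count). An unobserved first-order Markov chain *S<sub>t</sub>* on
*N* ∈ {2, 3, 4} states drives the observations through state-dependent
distributions,

- duration | S = s ~ Gamma(μ<sub>dur,s</sub>, σ<sub>dur,s</sub>)
- max depth | S = s ~ Gamma(μ<sub>dep,s</sub>, σ<sub>dep,s</sub>)
- buzz count | S = s ~ Poisson(λ<sub>s</sub>)

with the three variables mutually independent given the state
(contemporaneous conditional independence). The chain has transition matrix
Γ; optionally a whale-level discrete random effect replaces Γ with one of
*K* matrices Γ<sub>1..K</sub> drawn with probabilities ω, marginalised in
the likelihood:

ℓ = Σ<sub>w</sub> log Σ<sub>k</sub> ω<sub>k</sub> L<sub>w</sub>(Γ<sub>k</sub>),

where L<sub>w</sub> is the scaled forward-algorithm likelihood of whale
*w*'s dive sequence. Models are fitted by multi-start numerical maximum
likelihood (a large random scan of initial values, the best candidates
passed to `nlm`), compared by AIC/BIC across a ten-model catalogue, and the
selected model is decoded per whale with the Viterbi algorithm. Downstream
summaries include transition/bout structure, per-whale time budgets,
tag-duration regressions and noncentral-F power computations.

## Worked example

Simulate a 20-whale study from the default generating parameters (the
fitted study values), refit the 4-state model, and summarise:

```r
library(diveHMM)
sim <- simulate_study(n_whales = 20, seed = 42)   # 277 dives here
fit <- fit_dive_hmm(sim$dives, n_states = 4,
                    control = dive_hmm_control(seed = 1))
summary(fit)
#> Dive-classification hidden Markov model
#>   4 states, 1 mixture component, initial distribution: stationary
#>   log-likelihood -2962.672 on 32 parameters (277 dives, 20 whales)
#>   AIC 5989.34   BIC 6105.31   converged: TRUE
#>
#> State-dependent distributions (duration Gamma [min], depth Gamma [m], buzzes Poisson):
#>  state duration_mean duration_sd depth_mean depth_sd buzz_rate
#>      1          3.64        1.76       35.3     13.2      0.11
#>      2          7.06        3.23       89.4     40.2     11.62
#>      3         10.73        5.03      188.3     84.5      1.88
#>      4         16.78        8.23      578.6    278.2     30.98
#>
#> Transition matrix:
#>         to_1  to_2  to_3  to_4
#> from_1 0.613 0.232 0.141 0.014
#> from_2 0.043 0.781 0.120 0.057
#> from_3 0.177 0.059 0.746 0.019
#> from_4 0.092 0.041 0.185 0.682
```

State 1 is the shallow, short, buzz-free dive type; state 4 the deep, long,
buzz-rich one (states are always reported in ascending depth order). The
diagonal of the transition matrix dominating every row is the bout
structure: whales persist in a dive type rather than switching. Decoding
and the per-whale state frequencies:

```r
alloc <- allocate_states(fit)
alloc$totals                     # dives per state: 58 88 101 30
state_proportions(alloc$counts)  # per-whale frequencies vs the even 1/N
regression_power(3, 16, 0.35)    # 0.48: power of the states regression
```

A catalogue comparison (`run_catalogue()` + `select_model()`) reproduces
the model-selection step, and `run_pipeline()` chains
simulate → fit → decode → budget → report into one reproducible run with a
seed-stamped manifest.

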