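test_that("forward likelihood reduces correctly in degenerate cases", {
  set.seed(11)
  # N = 1: iid observations
  em <- emission_params(5, 2, 100, 40, 3)
  p1 <- hmm_params(matrix(1, 1, 1), em)
  d <- toy_dives("a", runif(6, 2, 10), runif(6, 30, 300), rpois(6, 3))
  expect_equal(forward_loglik(d, p1),
               sum(state_logdensity(d$duration_min, d$max_depth_m,
                                    d$n_buzzes, em, state = 1)))
  # T = 1: log sum_i delta_i f_i(x1)
  p2 <- random_params(3, delta_mode = "estimated")
  d1 <- d[1, ]
  ld <- state_logdensity(d1$duration_min, d1$max_depth_m, d1$n_buzzes,
                         p2$emissions)
  expect_equal(forward_loglik(d1, p2), log(sum(p2$delta * exp(ld))))
})

test_that("forward likelihood matches exhaustive path enumeration", {
  set.seed(12)
  for (rep in 1:5) {
    p <- random_params(2, delta_mode = "estimated")
    d <- toy_dives("a", runif(4, 2, 15), runif(4, 25, 500), rpois(4, 4))
    ld <- state_logdensity(d$duration_min, d$max_depth_m, d$n_buzzes,
                           p$emissions)
    expect_equal(forward_loglik(d, p),
                 enum_loglik(ld, p$Gamma[, , 1], p$delta),
                 tolerance = 1e-10)
  }
})

test_that("mixture likelihood degenerates and enumerates correctly", {
  set.seed(13)
  d <- toy_dives(rep(c("a", "b"), each = 3),
                 runif(6, 2, 15), runif(6, 25, 500), rpois(6, 4))
  # K = 1 equals the sum of per-whale forward log-likelihoods
  p <- random_params(3)
  expect_equal(mixture_loglik(d, p),
               forward_loglik(d[d$whale_id == "a", ], p) +
                 forward_loglik(d[d$whale_id == "b", ], p))
  # omega = (1, 0) equals the K = 1 likelihood of component 1
  p2 <- random_params(2, K = 2)
  p2$omega <- c(1, 0)
  p2a <- hmm_params(matrix(p2$Gamma[, , 1], 2, 2), p2$emissions)
  expect_equal(mixture_loglik(d, p2), mixture_loglik(d, p2a))
  # K = 2 against the explicit double sum over components and paths
  p3 <- random_params(2, K = 2, delta_mode = "estimated")
  manual <- 0
  for (w in c("a", "b")) {
    dw <- d[d$whale_id == w, ]
    ld <- state_logdensity(dw$duration_min, dw$max_depth_m, dw$n_buzzes,
                           p3$emissions)
    lw <- vapply(1:2, function(k)
      log(p3$omega[k]) + enum_loglik(ld, p3$Gamma[, , k], p3$delta),
      numeric(1))
    manual <- manual + log(sum(exp(lw)))
  }
  expect_equal(mixture_loglik(d, p3), manual, tolerance = 1e-10)
  # invariant breaches error
  bad <- p3
  bad$omega <- c(0.7, 0.7)
  expect_error(mixture_loglik(d, bad), "omega")
})

test_that("likelihood is invariant to state relabelling", {
  set.seed(14)
  d <- toy_dives("a", runif(8, 2, 15), runif(8, 25, 500), rpois(8, 4))
  p <- random_params(3, delta_mode = "estimated")
  ll <- mixture_loglik(d, p)
  perm <- c(3, 1, 2)
  em <- p$emissions[perm, ]
  em$state <- 1:3
  pp <- hmm_params(p$Gamma[perm, perm, 1, drop = FALSE], em,
                   delta = p$delta[perm])
  expect_equal(mixture_loglik(d, pp), ll, tolerance = 1e-12)
})

test_that("the fast likelihood path agrees with the reference one", {
  set.seed(15)
  sim <- simulate_study(n_whales = 4, dive_counts = c(3, 10, 1, 25),
                        seed = 16)
  for (cfg in list(c(2, 1), c(4, 1), c(3, 2))) {
    p <- random_params(cfg[1], cfg[2])
    llfn <- diveHMM:::make_loglik_fn(sim$dives, cfg[1], cfg[2])
    expect_equal(llfn(diveHMM:::emission_matrix(p), p$Gamma, p$omega),
                 mixture_loglik(sim$dives, p), tolerance = 1e-8)
  }
})

test_that("information criteria follow their definitions", {
  ic <- information_criteria(0, 1, exp(2))
  expect_equal(unname(ic), c(2, 2))
  # monotone in the parameter count at fixed likelihood
  ic1 <- information_criteria(50, 10, 259)
  ic2 <- information_criteria(50, 11, 259)
  expect_true(all(ic2 > ic1))
  # parameter accounting: 4 states, no random effects, stationary start
  expect_equal(n_hmm_params(4, 1), 4 * 3 + 4 * 5)
  expect_equal(n_hmm_params(3, 2, "estimated"), 15 + 2 * 6 + 1 + 2)
  expect_error(information_criteria(0, 0, 10))
})

test_that("stationary distributions solve delta Gamma = delta", {
  expect_equal(stationary_distribution(matrix(c(0.7, 0.3, 0.3, 0.7), 2)),
               c(0.5, 0.5))
  G <- table2_matrix()
  d <- stationary_distribution(G)
  expect_equal(as.numeric(d %*% G), d, tolerance = 1e-12)
  expect_equal(d, power_iter_stationary(G), tolerance = 1e-10)
  # permutation equivariance
  perm <- c(2, 4, 1, 3)
  expect_equal(stationary_distribution(G[perm, perm]), d[perm],
               tolerance = 1e-12)
  expect_error(stationary_distribution(diag(2) * 0.5), "sum to 1")
  expect_error(stationary_distribution(diag(2)), "reducible")
})

test_that("the Viterbi score never exceeds the forward likelihood", {
  set.seed(17)
  for (rep in 1:5) {
    N <- sample(2:4, 1)
    p <- random_params(N)
    d <- toy_dives("a", runif(12, 2, 15), runif(12, 25, 500), rpois(12, 4))
    ll <- forward_loglik(d, p)
    v <- viterbi(p, d)[[1]]
    expect_lte(v$score, ll)
    expect_lte(ll, v$score + nrow(d) * log(N))
  }
})
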