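# Two well-separated states used across the fitting tests: shallow/short/
# quiet vs deep/long/buzzy.
two_state_params <- function() {
  hmm_params(
    Gamma = matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE),
    emissions = emission_params(duration_mean = c(3, 14),
                                duration_sd = c(1.5, 7),
                                depth_mean = c(30, 400),
                                depth_sd = c(15, 200),
                                buzz_rate = c(0.1, 15))
  )
}

small_control <- function(seed)
  dive_hmm_control(n_initial_scan = 200, n_optimized = 3, seed = seed)

test_that("the initial-value scan is deterministic, ranked, and effective", {
  sim <- simulate_study(n_whales = 5, dive_counts = rep(30, 5),
                        params = two_state_params(), seed = 20)
  ctrl <- dive_hmm_control(n_initial_scan = 2000, n_optimized = 10, seed = 21)
  sc1 <- scan_initial_values(sim$dives, 2, control = ctrl)
  sc2 <- scan_initial_values(sim$dives, 2, control = ctrl)
  expect_identical(sc1, sc2)
  lls <- vapply(sc1, `[[`, numeric(1), "loglik")
  expect_true(all(diff(lls) <= 0))
  # best scanned candidate comes within 5% of the generating-parameter fit
  ll_gen <- mixture_loglik(sim$dives, two_state_params())
  expect_lt(abs(lls[1] - ll_gen) / abs(ll_gen), 0.05)
})

test_that("maximum likelihood recovers well-separated generating values", {
  gen <- two_state_params()
  sim <- simulate_study(n_whales = 20, dive_counts = rep(30, 20),
                        params = gen, seed = 22)
  fit <- fit_dive_hmm(sim$dives, 2, control = small_control(23))
  expect_true(fit$converged)
  # ML dominance over the generating parameters on the same data
  expect_gte(fit$loglik, mixture_loglik(sim$dives, gen))
  # emission means within 10% of truth
  expect_equal(fit$params$emissions$duration_mean,
               gen$emissions$duration_mean, tolerance = 0.1)
  expect_equal(fit$params$emissions$depth_mean,
               gen$emissions$depth_mean, tolerance = 0.1)
  expect_equal(fit$params$emissions$buzz_rate[2],
               gen$emissions$buzz_rate[2], tolerance = 0.1)
  # refitting from the returned optimum does not move the likelihood
  refit <- fit_dive_hmm(sim$dives, 2, control = small_control(23),
                        candidates = list(list(params = fit$params,
                                               loglik = fit$loglik)))
  expect_equal(refit$nll, fit$nll, tolerance = 1e-6)
  # the optimum improves on the best scanned start
  expect_lte(fit$nll, -max(fit$starts$start_loglik) + 1e-8)
})

test_that("fitted states come out in canonical depth order", {
  set.seed(24)
  p <- random_params(4)
  perm <- c(3, 1, 4, 2)
  em <- p$emissions[perm, ]; em$state <- 1:4
  scrambled <- hmm_params(p$Gamma[perm, perm, 1, drop = FALSE], em)
  fixed <- canonical_state_order(scrambled)
  expect_equal(fixed$emissions$depth_mean, sort(em$depth_mean))
  expect_equal(fixed$Gamma, p$Gamma)
  # likelihood untouched by relabelling
  d <- toy_dives("a", runif(6, 2, 15), runif(6, 25, 600), rpois(6, 3))
  expect_equal(mixture_loglik(d, fixed), mixture_loglik(d, scrambled),
               tolerance = 1e-12)
})

test_that("model selection is an AIC argmin with a disagreement flag", {
  stub <- function(aic, bic)
    structure(list(aic = aic, bic = bic, n_states = 2, n_mixture = 1),
              class = "dive_hmm")
  fits <- list(a = stub(100, 120), b = stub(90, 125), c = NULL)
  expect_warning(best <- select_model(fits), "failed|AIC and BIC")
  expect_equal(best$aic, 90)
  expect_true(attr(best, "aic_bic_disagree"))
  agree <- list(a = stub(100, 120), b = stub(90, 110))
  best2 <- select_model(agree)
  expect_false(attr(best2, "aic_bic_disagree"))
  expect_error(select_model(list(NULL)), "no successful fits")
})

test_that("the catalogue lists ten model specifications", {
  cat10 <- default_catalogue()
  expect_equal(nrow(cat10), 10)
  expect_equal(sum(cat10$n_mixture == 1), 3)
  expect_true(all(cat10$n_states %in% 2:4))
})

test_that("repeated fits of a well-separated model are numerically stable", {
  sim <- simulate_study(n_whales = 8, dive_counts = rep(25, 8),
                        params = two_state_params(), seed = 26)
  rep <- stability_check(sim$dives, 2, control = small_control(27),
                         n_runs = 3)
  expect_equal(nrow(rep$runs), 3)
  expect_lt(rep$nll_spread, 1e-3)
  expect_equal(rep$allocation_agreement, 1)
})
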