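test_that("time budgets partition the record into surface and state hours", {
  # whale with no dives: all surface
  empty <- dive_table(character(0), numeric(0), numeric(0), numeric(0),
                      numeric(0), integer(0))
  b0 <- time_budget(empty, integer(0), record_h = 3, n_states = 4)
  expect_equal(b0$surface_prop, 1)

  # two 30-minute dives in a 2 h record, states 1 and 3
  d <- toy_dives("a", c(30, 30), c(100, 300), c(0, 5))
  b <- time_budget(d, c(1L, 3L), record_h = 2, n_states = 4)
  expect_equal(c(b$state1_prop, b$state2_prop, b$state3_prop, b$state4_prop),
               c(0.25, 0, 0.25, 0))
  expect_equal(b$surface_prop, 0.5)

  expect_error(time_budget(d, c(1L), record_h = 2, n_states = 4),
               "not aligned")
  expect_error(time_budget(d, c(1L, 3L), record_h = 0.5, n_states = 4),
               "exceeds")
})

test_that("synthetic budgets equal the generator's ground-truth occupancy", {
  sim <- simulate_study(n_whales = 6, dive_counts = rep(20, 6), seed = 40)
  budgets <- study_time_budgets(sim$dives, sim$states, sim$records, 4)
  for (i in seq_len(6)) {
    w <- sim$records$whale_id[i]
    sel <- sim$dives$whale_id == w
    for (j in 1:4)
      expect_equal(budgets[[paste0("state", j, "_h")]][i],
                   sum(sim$dives$duration_min[sel][sim$states[sel] == j]) / 60)
    expect_equal(budgets$surface_h[i] +
                   sum(sim$dives$duration_min[sel]) / 60,
                 sim$records$record_h[i])
  }
  expect_true(all(budgets$surface_prop >= 0 & budgets$surface_prop <= 1))
})

test_that("the surface regression reports the classical OLS F test", {
  # perfectly collinear data
  x <- c(0.2, 0.4, 0.6, 0.8)
  r <- surface_regression(record_h = 2 + 3 * x, surface_prop = x)
  expect_equal(r$r_squared, 1)

  # 4-point fixture against hand normal-equations arithmetic
  y <- c(1, 3, 2, 5)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  ssr <- sum((b0 + b1 * x - mean(y))^2)
  sse <- sum((y - b0 - b1 * x)^2)
  r2 <- surface_regression(y, x)
  expect_equal(r2$r_squared, ssr / (ssr + sse))
  expect_equal(r2$f, (ssr / 1) / (sse / 2))
  expect_equal(c(r2$df1, r2$df2), c(1, 2))

  expect_error(surface_regression(y, rep(0.5, 4)), "zero variance")
  expect_error(surface_regression(1:2, c(0.1, 0.2)), "3 whales")
})

test_that("the null surface regression rejects at the nominal rate", {
  set.seed(41)
  x <- runif(20, 0, 1)
  pvals <- replicate(2000, {
    y <- rnorm(20)
    surface_regression(y, x)$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.015)
})

test_that("the states regression uses state-count groups correctly", {
  # equal group means: no explained variance
  r0 <- states_regression(c(1, 3, 5, 1, 3, 5), rep(c(1, 2), each = 3))
  expect_equal(r0$r_squared, 0)

  # two groups: overall F equals the squared two-sample t
  set.seed(42)
  h <- c(rnorm(6, 2), rnorm(7, 6))
  g <- c(rep(1, 6), rep(4, 7))
  r <- states_regression(h, g)
  tt <- t.test(h[g == 4], h[g == 1], var.equal = TRUE)
  expect_equal(r$f, unname(tt$statistic)^2)
  expect_equal(c(r$df1, r$df2), c(1, 11))

  # internal consistency: between-group SS over total SS equals R^2
  set.seed(43)
  h2 <- rnorm(12, rep(c(2, 4, 9), each = 4))
  g2 <- rep(c(1, 2, 4), each = 4)
  r2 <- states_regression(h2, g2)
  gm <- tapply(h2, g2, mean)[as.character(g2)]
  expect_equal(r2$r_squared,
               sum((gm - mean(h2))^2) / sum((h2 - mean(h2))^2))
  expect_warning(states_regression(h2, g2), "dropped")
})

test_that("regression power follows the noncentral F formula", {
  # zero effect: power equals the significance level
  expect_equal(regression_power(1, 18, 0, 0.05), 0.05)
  expect_equal(regression_power(3, 16, 0, 0.1), 0.1)
  # strictly increasing in effect size and denominator df
  f2s <- seq(0, 1, by = 0.1)
  expect_true(all(diff(regression_power(1, 18, f2s)) > 0))
  vs <- c(5, 10, 20, 40, 100)
  expect_true(all(diff(vapply(vs, function(v)
    regression_power(1, v, 0.35), numeric(1))) > 0))
  # definition check against direct noncentral-F tail arithmetic
  expect_equal(regression_power(2, 12, 0.4),
               1 - pf(qf(0.95, 2, 12), 2, 12, ncp = 0.4 * 15))
})
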