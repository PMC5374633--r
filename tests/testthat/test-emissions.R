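test_that("the joint log-density is the sum of its three factors", {
  em <- emission_params(duration_mean = c(3, 10), duration_sd = c(1.5, 5),
                        depth_mean = c(30, 200), depth_sd = c(15, 100),
                        buzz_rate = c(2, 20))
  # Poisson factor at k = 0, lambda = 2 contributes exactly -2 in log space
  ld <- state_logdensity(4, 50, 0, em, state = 1)
  gd <- gamma_shape_scale(3, 1.5); gz <- gamma_shape_scale(30, 15)
  gamma_part <- dgamma(4, gd$shape, scale = gd$scale, log = TRUE) +
    dgamma(50, gz$shape, scale = gz$scale, log = TRUE)
  expect_equal(ld - gamma_part, -2)

  # structural conditional independence on a full matrix
  set.seed(1)
  dur <- runif(10, 1, 20); dep <- runif(10, 25, 600); bz <- rpois(10, 5)
  full <- state_logdensity(dur, dep, bz, em)
  for (s in 1:2) {
    e <- em[s, ]
    g1 <- gamma_shape_scale(e$duration_mean, e$duration_sd)
    g2 <- gamma_shape_scale(e$depth_mean, e$depth_sd)
    expect_equal(full[, s],
                 dgamma(dur, g1$shape, scale = g1$scale, log = TRUE) +
                   dgamma(dep, g2$shape, scale = g2$scale, log = TRUE) +
                   dpois(bz, e$buzz_rate, log = TRUE))
  }
})

test_that("mean = sd gives the exponential special case", {
  em <- emission_params(5, 5, 100, 50, 1)
  x <- c(0.5, 3, 12)
  ld <- state_logdensity(x, rep(100, 3), rep(0L, 3), em, state = 1)
  gz <- gamma_shape_scale(100, 50)
  dur_part <- ld - dgamma(100, gz$shape, scale = gz$scale, log = TRUE) -
    dpois(0, 1, log = TRUE)
  expect_equal(dur_part, log(1 / 5) - x / 5)
})

test_that("each marginal integrates (or sums) to one", {
  set.seed(21)
  m1 <- runif(1, 2, 15); s1 <- runif(1, 1, 6)
  m2 <- runif(1, 30, 400); s2 <- runif(1, 10, 150)
  lam <- runif(1, 0.1, 25)
  em <- emission_params(m1, s1, m2, s2, lam)
  # quadrature over fine grids for the Gammas, exhaustive series for Poisson
  g1 <- seq(1e-4, m1 + 30 * s1, length.out = 2e5)
  g2 <- seq(1e-4, m2 + 30 * s2, length.out = 2e5)
  base <- state_logdensity(g1, rep(m2, length(g1)), rep(0L, length(g1)), em,
                           state = 1)
  p2 <- gamma_shape_scale(m2, s2)
  dur_dens <- exp(base - dgamma(m2, p2$shape, scale = p2$scale, log = TRUE) -
                    dpois(0L, lam, log = TRUE))
  expect_equal(sum(dur_dens) * diff(g1[1:2]), 1, tolerance = 1e-3)
  p1 <- gamma_shape_scale(m1, s1)
  dep_dens <- exp(
    state_logdensity(rep(m1, length(g2)), g2, rep(0L, length(g2)), em, 1) -
      dgamma(m1, p1$shape, scale = p1$scale, log = TRUE) -
      dpois(0L, lam, log = TRUE))
  expect_equal(sum(dep_dens) * diff(g2[1:2]), 1, tolerance = 1e-3)
  ks <- 0:500
  pois_mass <- exp(
    state_logdensity(rep(m1, length(ks)), rep(m2, length(ks)), ks, em, 1) -
      dgamma(m1, p1$shape, scale = p1$scale, log = TRUE) -
      dgamma(m2, p2$shape, scale = p2$scale, log = TRUE))
  expect_equal(sum(pois_mass), 1, tolerance = 1e-12)
})

test_that("invalid observations are handled as specified", {
  em <- emission_params(5, 2, 100, 50, 2)
  expect_error(state_logdensity(5, 100, 1.5, em), "integer")
  expect_warning(ld <- state_logdensity(c(-1, 5), c(100, 100), c(0L, 0L), em),
                 "non-positive")
  expect_equal(ld[1, 1], -Inf)
  expect_true(is.finite(ld[2, 1]))
})

test_that("working-scale transforms invert exactly", {
  set.seed(33)
  for (cfg in list(c(2, 1), c(3, 2), c(4, 3))) {
    p <- random_params(cfg[1], cfg[2])
    w <- natural_to_working(p)
    q <- working_to_natural(w, cfg[1], cfg[2])
    expect_equal(q$Gamma, p$Gamma, tolerance = 1e-12)
    expect_equal(q$omega, p$omega, tolerance = 1e-12)
    expect_equal(as.matrix(q$emissions), as.matrix(p$emissions),
                 tolerance = 1e-12)
  }
  p <- random_params(3, 1, delta_mode = "estimated")
  q <- working_to_natural(natural_to_working(p), 3, 1, "estimated")
  expect_equal(q$delta, p$delta, tolerance = 1e-12)

  # all-zero working vector: emission parameters 1, uniform rows
  z <- working_to_natural(rep(0, n_hmm_params(2, 1) ), 2, 1)
  expect_equal(unname(as.matrix(z$emissions)[, -1]), matrix(1, 2, 5))
  expect_equal(z$Gamma[, , 1], matrix(0.5, 2, 2))

  expect_error(working_to_natural(c(1, NA), 2, 1), "non-finite")
})

test_that("each working coordinate controls exactly one emission parameter", {
  p <- random_params(3)
  w <- natural_to_working(p)
  for (i in c(1, 7, 15)) {                    # probe a few emission slots
    w2 <- w
    w2[i] <- w2[i] + 0.3
    q <- working_to_natural(w2, 3, 1)
    em0 <- as.matrix(p$emissions)[, -1]
    em1 <- as.matrix(q$emissions)[, -1]
    changed <- abs(t(em1) - t(em0)) > 1e-12   # state-major layout
    expect_equal(sum(changed), 1)
    expect_true(as.numeric(t(em1))[i] > as.numeric(t(em0))[i])
  }
})

test_that("parameter files round-trip at full precision", {
  set.seed(4)
  p <- random_params(4, 2)
  f <- tempfile(fileext = ".txt")
  write_hmm_params(p, f)
  q <- read_hmm_params(f)
  expect_identical(q$Gamma, p$Gamma)
  expect_identical(q$omega, p$omega)
  expect_equal(as.data.frame(q$emissions), as.data.frame(p$emissions))
})

test_that("gamma mean/sd parameterisation inverts", {
  set.seed(5)
  m <- runif(10, 0.1, 100); s <- runif(10, 0.1, 50)
  p <- gamma_shape_scale(m, s)
  expect_equal(p$shape * p$scale, m)
  expect_equal(sqrt(p$shape) * p$scale, s)
})
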