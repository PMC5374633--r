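## Likelihood machinery. The hidden process is a first-order Markov chain on
## N in {2,3,4} states (N = 1 is allowed as the iid degenerate case). With
## discrete random effects, each whale carries one of K transition matrices
## drawn with probabilities omega, shared emission parameters across
## components, and the component membership is marginalised in the
## likelihood, never hard-assigned.

#' Construct and validate HMM parameters
#'
#' @param Gamma an N x N row-stochastic transition matrix, or an N x N x K
#'   array of them when the model carries K mixture components (discrete
#'   random effects on the transition probabilities).
#' @param emissions an [emission_params] table with N rows.
#' @param omega mixture weights, length K, summing to 1.
#' @param delta either the string `"stationary"` (initial distribution of each
#'   component is the stationary distribution of its transition matrix) or a
#'   probability vector of length N shared across components.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(Gamma, emissions, omega = 1, delta = "stationary") {
  if (is.matrix(Gamma)) Gamma <- array(Gamma, c(nrow(Gamma), ncol(Gamma), 1))
  N <- dim(Gamma)[1]
  K <- dim(Gamma)[3]
  stationary <- identical(delta, "stationary")
  p <- structure(list(
    n_states = N, n_mixture = K, Gamma = Gamma,
    omega = as.numeric(omega),
    delta_mode = if (stationary) "stationary" else "estimated",
    delta = if (stationary) NULL else as.numeric(delta),
    emissions = emissions
  ), class = "hmm_params")
  validate_hmm_params(p)
}

validate_hmm_params <- function(p, tol = 1e-10) {
  N <- p$n_states; K <- p$n_mixture
  if (dim(p$Gamma)[1] != N || dim(p$Gamma)[2] != N || dim(p$Gamma)[3] != K)
    stop("Gamma must be an N x N x K array")
  for (k in seq_len(K)) {
    G <- p$Gamma[, , k, drop = TRUE]
    if (N == 1) G <- matrix(G, 1, 1)
    if (any(G < 0) || any(G > 1) || any(abs(rowSums(G) - 1) > tol))
      stop("transition matrix ", k,
           " is not row-stochastic (rows must sum to 1 within ", tol, ")")
  }
  if (length(p$omega) != K || any(p$omega < 0) ||
      abs(sum(p$omega) - 1) > tol)
    stop("omega must be length K, non-negative, summing to 1")
  if (p$delta_mode == "estimated") {
    if (length(p$delta) != N || any(p$delta < 0) ||
        abs(sum(p$delta) - 1) > tol)
      stop("delta must be a length-N probability vector")
  }
  validate_emission_params(p$emissions)
  if (nrow(p$emissions) != N)
    stop("emission table must have one row per state")
  invisible(p)
}

#' Stationary distribution of a transition matrix
#'
#' Solves \eqn{\delta \Gamma = \delta, \sum\delta = 1} as a linear system.
#'
#' @param Gamma a row-stochastic matrix, irreducible and aperiodic.
#' @param tol tolerance for detecting a numerically singular (reducible)
#'   chain.
#' @return the stationary probability vector.
#' @export
stationary_distribution <- function(Gamma, tol = 1e-10) {
  N <- nrow(Gamma)
  if (any(abs(rowSums(Gamma) - 1) > 1e-8))
    stop("Gamma rows must sum to 1")
  if (N == 1) return(1)
  A <- rbind(t(diag(N) - Gamma), rep(1, N))
  delta <- tryCatch(
    as.numeric(qr.solve(A, c(rep(0, N), 1), tol = tol)),
    error = function(e) stop("chain appears reducible or periodic: ",
                             conditionMessage(e))
  )
  if (any(delta < -1e-8))
    stop("chain appears reducible or periodic: negative stationary mass")
  delta <- pmax(delta, 0)
  delta / sum(delta)
}

component_delta <- function(params, k) {
  if (params$delta_mode == "estimated") return(params$delta)
  stationary_distribution(matrix(params$Gamma[, , k],
                                 params$n_states, params$n_states))
}

#' Forward-algorithm log-likelihood of one dive sequence
#'
#' Exact HMM log-likelihood of a single whale's ordered dives under a single
#' transition matrix, computed by the scaled forward recursion (numerically
#' stable for long sequences and widely separated densities).
#'
#' @param dives a data.frame with columns `duration_min`, `max_depth_m`,
#'   `n_buzzes` for one whale, in time order.
#' @param params an [hmm_params] object with `n_mixture == 1` (or a component
#'   selected via `component`).
#' @param component which mixture component's transition matrix to use.
#' @return the log-likelihood scalar.
#' @export
forward_loglik <- function(dives, params, component = 1L) {
  params <- validate_hmm_params(params)
  if (nrow(dives) == 0) stop("empty dive sequence")
  ld <- state_logdensity(dives$duration_min, dives$max_depth_m,
                         dives$n_buzzes, params$emissions)
  N <- params$n_states
  forward_loglik_cpp(ld, matrix(params$Gamma[, , component], N, N),
                     component_delta(params, component))
}

## Internal fast path: per-whale log-density blocks precomputed once per
## likelihood evaluation, shared across mixture components.
loglik_from_logdens <- function(ld_list, params) {
  N <- params$n_states; K <- params$n_mixture
  Gk <- lapply(seq_len(K), function(k) matrix(params$Gamma[, , k], N, N))
  dk <- lapply(seq_len(K), function(k) component_delta(params, k))
  total <- 0
  for (ld in ld_list) {
    lls <- vapply(seq_len(K), function(k)
      forward_loglik_cpp(ld, Gk[[k]], dk[[k]]), numeric(1))
    lw <- log(params$omega) + lls
    m <- max(lw)
    if (!is.finite(m)) return(-Inf)
    total <- total + m + log(sum(exp(lw - m)))
  }
  total
}

#' Mixture (random-effects) log-likelihood over all whales
#'
#' Total log-likelihood of a dive table under a whale-level finite mixture of
#' K transition matrices with shared emissions: each whale's component
#' membership is marginalised,
#' \eqn{\ell = \sum_w \log \sum_k \omega_k L_w(\Gamma_k)}, with the inner sum
#' log-sum-exp stabilised. With `K = 1` this reduces to the sum of per-whale
#' forward log-likelihoods.
#'
#' @param dives a dive table (see [dive_table()]) covering one or more whales;
#'   rows must be in time order within whale.
#' @param params an [hmm_params] object.
#' @return the total log-likelihood.
#' @export
mixture_loglik <- function(dives, params) {
  params <- validate_hmm_params(params)
  if (nrow(dives) == 0) stop("empty dive table")
  ld <- state_logdensity(dives$duration_min, dives$max_depth_m,
                         dives$n_buzzes, params$emissions)
  ld_list <- split.data.frame(ld, factor(dives$whale_id,
                                         levels = unique(dives$whale_id)))
  loglik_from_logdens(ld_list, params)
}

## Fast likelihood closure used by scanning and optimization: precomputes the
## data-dependent parts of the three log-densities (log durations/depths,
## log-factorials of buzz counts, whale block lengths) so one evaluation is a
## handful of vectorised operations plus a single C++ pass over all whales
## and mixture components. Agrees with mixture_loglik() to rounding.
make_loglik_fn <- function(dives, n_states, n_mixture) {
  N <- n_states; K <- n_mixture
  lens <- as.integer(lengths(split_by_whale(dives)))
  x1 <- dives$duration_min; lx1 <- log(x1)
  x2 <- dives$max_depth_m; lx2 <- log(x2)
  kk <- dives$n_buzzes; lgk <- lgamma(kk + 1)
  Tn <- nrow(dives)
  function(em, Gamma, omega, delta = NULL) {
    ld <- matrix(0, Tn, N)
    for (j in seq_len(N)) {
      a1 <- em[j, 1]^2 / em[j, 2]^2; s1 <- em[j, 2]^2 / em[j, 1]
      a2 <- em[j, 3]^2 / em[j, 4]^2; s2 <- em[j, 4]^2 / em[j, 3]
      lam <- em[j, 5]
      ld[, j] <- (a1 - 1) * lx1 - x1 / s1 - lgamma(a1) - a1 * log(s1) +
        (a2 - 1) * lx2 - x2 / s2 - lgamma(a2) - a2 * log(s2) +
        kk * log(lam) - lam - lgk
    }
    deltas <- matrix(0, K, N)
    for (k in seq_len(K))
      deltas[k, ] <- if (is.null(delta))
        stationary_distribution(matrix(Gamma[, , k], N, N)) else delta
    mixture_loglik_groups_cpp(ld, lens, as.numeric(Gamma), N, K,
                              as.numeric(omega), deltas)
  }
}

emission_matrix <- function(params) {
  as.matrix(params$emissions[c("duration_mean", "duration_sd", "depth_mean",
                               "depth_sd", "buzz_rate")])
}

## Minimal working-scale decoder for the optimizer's inner loop; same layout
## as working_to_natural() without object construction or validation.
decode_working <- function(w, N, K, delta_mode) {
  n_em <- 5L * N
  em <- matrix(exp(w[seq_len(n_em)]), nrow = N, byrow = TRUE)
  Gamma <- array(0, c(N, N, K))
  pos <- n_em
  for (k in seq_len(K)) {
    for (i in seq_len(N)) {
      row <- rep(1, N)
      row[-i] <- exp(w[pos + seq_len(N - 1L)])
      pos <- pos + N - 1L
      Gamma[i, , k] <- row / sum(row)
    }
  }
  omega <- if (K > 1) {
    o <- c(1, exp(w[pos + seq_len(K - 1L)])); pos <- pos + K - 1L
    o / sum(o)
  } else 1
  delta <- NULL
  if (delta_mode == "estimated") {
    d <- c(1, exp(w[pos + seq_len(N - 1L)]))
    delta <- d / sum(d)
  }
  list(em = em, Gamma = Gamma, omega = omega, delta = delta)
}

#' Akaike and Bayesian information criteria
#'
#' `aic = 2 nll + 2 p`, `bic = 2 nll + p log(n)`.
#'
#' @param nll negative log-likelihood.
#' @param n_params number of free parameters (p >= 1).
#' @param n_obs number of observations (n >= 2); for these models the
#'   observations are dives, so the default accounting uses the total dive
#'   count.
#' @return named vector `c(aic, bic)`.
#' @export
information_criteria <- function(nll, n_params, n_obs) {
  stopifnot(n_params >= 1, n_obs >= 2)
  c(aic = 2 * nll + 2 * n_params, bic = 2 * nll + n_params * log(n_obs))
}

#' Number of free parameters of a model specification
#'
#' Per state: 5 emission parameters (two Gamma mean/sd pairs and a Poisson
#' rate). Per mixture component: N(N-1) free transition probabilities; K-1
#' free mixture weights; N-1 initial-distribution parameters when the initial
#' distribution is estimated rather than tied to stationarity.
#'
#' @param n_states,n_mixture model dimensions.
#' @param delta_mode `"stationary"` or `"estimated"`.
#' @return integer parameter count.
#' @export
n_hmm_params <- function(n_states, n_mixture = 1L,
                         delta_mode = "stationary") {
  N <- n_states; K <- n_mixture
  5L * N + K * N * (N - 1L) + (K - 1L) +
    if (delta_mode == "estimated") N - 1L else 0L
}
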