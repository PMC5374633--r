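# Independent brute-force oracles, deliberately naive: these re-derive the
# quantities the package computes by dynamic programming or linear algebra,
# by exhaustive enumeration, so the two routes share no code.

# log-likelihood by summing over every possible state path
enum_loglik <- function(ld, Gamma, delta) {
  N <- ncol(ld)
  T_ <- nrow(ld)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  lp <- apply(paths, 1, function(s) {
    out <- log(delta[s[1]]) + ld[1, s[1]]
    if (T_ > 1)
      for (t in 2:T_)
        out <- out + log(Gamma[s[t - 1], s[t]]) + ld[t, s[t]]
    out
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# most probable state path by enumeration (assumes no exact ties)
enum_viterbi <- function(ld, Gamma, delta) {
  N <- ncol(ld)
  T_ <- nrow(ld)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  lp <- apply(paths, 1, function(s) {
    out <- log(delta[s[1]]) + ld[1, s[1]]
    if (T_ > 1)
      for (t in 2:T_)
        out <- out + log(Gamma[s[t - 1], s[t]]) + ld[t, s[t]]
    out
  })
  list(states = as.integer(paths[which.max(lp), ]), score = max(lp))
}

# dive intervals by a literal sample-by-sample scan
scan_segments <- function(depth, threshold) {
  runs <- list()
  inside <- FALSE
  for (i in seq_along(depth)) {
    if (depth[i] >= threshold && !inside) {
      runs[[length(runs) + 1]] <- c(i, i)
      inside <- TRUE
    } else if (depth[i] >= threshold) {
      runs[[length(runs)]][2] <- i
    } else inside <- FALSE
  }
  runs
}

# stationary distribution by power iteration
power_iter_stationary <- function(Gamma, iters = 10000) {
  d <- rep(1 / nrow(Gamma), nrow(Gamma))
  for (i in seq_len(iters)) d <- as.numeric(d %*% Gamma)
  d / sum(d)
}

# random valid parameter set for property tests
random_params <- function(N, K = 1, delta_mode = "stationary") {
  em <- emission_params(
    duration_mean = runif(N, 2, 20), duration_sd = runif(N, 1, 8),
    depth_mean = sort(runif(N, 25, 700)), depth_sd = runif(N, 10, 200),
    buzz_rate = runif(N, 0.05, 30)
  )
  G <- array(0, c(N, N, K))
  for (k in seq_len(K))
    for (i in seq_len(N)) {
      r <- rgamma(N, 1) + (seq_len(N) == i) * 3
      G[i, , k] <- r / sum(r)
    }
  om <- if (K > 1) {o <- rgamma(K, 1); o / sum(o)} else 1
  de <- if (delta_mode == "estimated") {d <- rgamma(N, 1); d / sum(d)}
  else "stationary"
  hmm_params(Gamma = G, emissions = em, omega = om, delta = de)
}

# small dive table with arbitrary (valid) values
toy_dives <- function(whale_id, duration, depth, buzzes) {
  start <- cumsum(c(0, duration[-length(duration)] * 60 + 300))
  # restart the clock for each whale
  for (w in unique(whale_id)) {
    i <- which(whale_id == w)
    start[i] <- start[i] - start[i[1]]
  }
  dive_table(whale_id, start, start + duration * 60, duration, depth, buzzes)
}

table2_matrix <- function() {
  G <- matrix(c(0.526, 0.168, 0.275, 0.030,
                0.040, 0.714, 0.134, 0.112,
                0.142, 0.087, 0.730, 0.041,
                0.069, 0.148, 0.140, 0.643), 4, 4, byrow = TRUE)
  G / rowSums(G)
}
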