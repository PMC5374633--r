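## State-dependent observation model: duration ~ Gamma, maximum depth ~ Gamma,
## buzz count ~ Poisson, mutually independent given the hidden state
## (contemporaneous conditional independence). Gamma distributions are
## parameterised by mean and sd user-side (shape = mean^2/sd^2,
## scale = sd^2/mean internally), because state summaries are reported as
## means; the likelihood is invariant to this choice.

#' Convert Gamma mean/sd to shape and scale
#'
#' @param mean,sd positive numerics (recycled).
#' @return list with components `shape` and `scale`.
#' @export
gamma_shape_scale <- function(mean, sd) {
  stopifnot(all(mean > 0), all(sd > 0))
  list(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Mean of a Gamma distribution with a given median and coefficient of variation
#'
#' Inverts the median of a Gamma(shape = 1/cv^2) numerically. Used to turn
#' reported per-state medians into generator means.
#'
#' @param median positive numeric.
#' @param cv coefficient of variation (sd/mean), default 0.5.
#' @return the mean.
#' @export
gamma_mean_from_median <- function(median, cv = 0.5) {
  stopifnot(median > 0, cv > 0)
  shape <- 1 / cv^2
  # median of Gamma(shape, scale) = scale * qgamma(0.5, shape, rate = 1)
  median * shape / stats::qgamma(0.5, shape = shape, rate = 1)
}

#' Construct a per-state emission parameter table
#'
#' @param duration_mean,duration_sd dive duration Gamma mean/sd (minutes).
#' @param depth_mean,depth_sd maximum-depth Gamma mean/sd (meters).
#' @param buzz_rate Poisson mean buzz count per dive.
#' @return a data.frame with one row per state, class `emission_params`.
#' @export
emission_params <- function(duration_mean, duration_sd, depth_mean, depth_sd,
                            buzz_rate) {
  em <- data.frame(
    state = seq_along(duration_mean),
    duration_mean = duration_mean, duration_sd = duration_sd,
    depth_mean = depth_mean, depth_sd = depth_sd,
    buzz_rate = buzz_rate
  )
  validate_emission_params(em)
  class(em) <- c("emission_params", "data.frame")
  em
}

validate_emission_params <- function(em) {
  need <- c("duration_mean", "duration_sd", "depth_mean", "depth_sd",
            "buzz_rate")
  if (!all(need %in% names(em)))
    stop("emission table must have columns: ", paste(need, collapse = ", "))
  vals <- as.matrix(em[need])
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all emission parameters must be finite and strictly positive")
  invisible(em)
}

#' Per-state log-density of dive observations
#'
#' Sum of the Gamma log-density of duration, the Gamma log-density of maximum
#' depth, and the Poisson log-mass of the buzz count, per state. Non-positive
#' durations or depths get `-Inf` with a warning; non-integer buzz counts are
#' an error.
#'
#' @param duration,depth,n_buzzes observation vectors (equal length).
#' @param emissions an [emission_params] table.
#' @param state optional single state index; if `NULL` all states.
#' @return a `length(duration)` x N matrix of log-densities (or a vector when
#'   `state` is given).
#' @export
state_logdensity <- function(duration, depth, n_buzzes, emissions,
                             state = NULL) {
  validate_emission_params(emissions)
  if (any(n_buzzes != round(n_buzzes)))
    stop("buzz counts must be integers")
  bad <- duration <= 0 | depth <= 0
  if (any(bad))
    warning("non-positive duration or depth: log-density set to -Inf")
  states <- if (is.null(state)) seq_len(nrow(emissions)) else state
  out <- matrix(-Inf, length(duration), length(states))
  ok <- !bad
  for (j in seq_along(states)) {
    e <- emissions[states[j], ]
    gd <- gamma_shape_scale(e$duration_mean, e$duration_sd)
    gz <- gamma_shape_scale(e$depth_mean, e$depth_sd)
    out[ok, j] <-
      stats::dgamma(duration[ok], shape = gd$shape, scale = gd$scale,
                    log = TRUE) +
      stats::dgamma(depth[ok], shape = gz$shape, scale = gz$scale,
                    log = TRUE) +
      stats::dpois(n_buzzes[ok], lambda = e$buzz_rate, log = TRUE)
  }
  if (!is.null(state)) drop(out) else out
}

## ---- natural <-> working parameter transforms -------------------------------
## Unconstrained ("working") scale for the optimizer: log for positive emission
## parameters, multinomial logit (diagonal reference) for transition rows,
## logit-style log-ratio for mixture weights and an estimated initial
## distribution. Layout: [5N emissions][K * N(N-1) transitions][K-1 weights]
## [N-1 delta if estimated].

#' Map HMM parameters to the unconstrained working scale
#'
#' @param params an [hmm_params] object.
#' @return numeric vector; `working_to_natural()` inverts it exactly.
#' @export
natural_to_working <- function(params) {
  params <- validate_hmm_params(params)
  N <- params$n_states; K <- params$n_mixture
  em <- as.matrix(params$emissions[c("duration_mean", "duration_sd",
                                     "depth_mean", "depth_sd", "buzz_rate")])
  w <- as.numeric(t(log(em)))                      # state-major, 5 per state
  for (k in seq_len(K)) {
    G <- params$Gamma[, , k]
    for (i in seq_len(N))
      w <- c(w, log(G[i, -i] / G[i, i]))
  }
  if (K > 1) w <- c(w, log(params$omega[-1] / params$omega[1]))
  if (params$delta_mode == "estimated")
    w <- c(w, log(params$delta[-1] / params$delta[1]))
  if (!all(is.finite(w)))
    stop("parameters on the boundary (zero entries) have no working image")
  w
}

#' Map a working-scale vector back to natural HMM parameters
#'
#' @param w numeric vector laid out as produced by [natural_to_working()].
#' @param n_states,n_mixture model dimensions.
#' @param delta_mode `"stationary"` or `"estimated"`.
#' @return an [hmm_params] object.
#' @export
working_to_natural <- function(w, n_states, n_mixture = 1L,
                               delta_mode = "stationary") {
  if (!all(is.finite(w))) stop("non-finite working parameters")
  N <- n_states; K <- n_mixture
  n_em <- 5L * N
  n_tr <- K * N * (N - 1L)
  n_om <- if (K > 1) K - 1L else 0L
  n_de <- if (delta_mode == "estimated") N - 1L else 0L
  if (length(w) != n_em + n_tr + n_om + n_de)
    stop("working vector has length ", length(w), ", expected ",
         n_em + n_tr + n_om + n_de)
  em <- matrix(exp(w[seq_len(n_em)]), nrow = N, byrow = TRUE)
  emissions <- emission_params(em[, 1], em[, 2], em[, 3], em[, 4], em[, 5])
  Gamma <- array(0, c(N, N, K))
  pos <- n_em
  for (k in seq_len(K)) {
    for (i in seq_len(N)) {
      tau <- w[pos + seq_len(N - 1L)]
      pos <- pos + N - 1L
      row <- rep(1, N)
      row[-i] <- exp(tau)
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
  hmm_params(Gamma = Gamma, emissions = emissions, omega = omega,
             delta = if (delta_mode == "estimated") delta else "stationary")
}

## ---- parameter files --------------------------------------------------------

#' Write/read HMM parameters as structured key-value text
#'
#' Full-precision round trip: `read_hmm_params(write_hmm_params(p, f))`
#' reproduces `p` exactly.
#'
#' @param params an [hmm_params] object.
#' @param path file path.
#' @return `write_hmm_params()` returns `path` invisibly; `read_hmm_params()`
#'   returns the [hmm_params].
#' @export
write_hmm_params <- function(params, path) {
  params <- validate_hmm_params(params)
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    paste("n_states:", params$n_states),
    paste("n_mixture:", params$n_mixture),
    paste("delta_mode:", params$delta_mode),
    paste("omega:", num(params$omega))
  )
  if (params$delta_mode == "estimated")
    lines <- c(lines, paste("delta:", num(params$delta)))
  for (s in seq_len(params$n_states)) {
    e <- params$emissions[s, ]
    lines <- c(lines, paste0("state ", s, ":"),
               paste("  duration_mean:", num(e$duration_mean)),
               paste("  duration_sd:", num(e$duration_sd)),
               paste("  depth_mean:", num(e$depth_mean)),
               paste("  depth_sd:", num(e$depth_sd)),
               paste("  buzz_rate:", num(e$buzz_rate)))
  }
  for (k in seq_len(params$n_mixture)) {
    lines <- c(lines, paste0("Gamma ", k, ":"))
    for (i in seq_len(params$n_states))
      lines <- c(lines, paste(" ", num(params$Gamma[i, , k])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hmm_params
#' @export
read_hmm_params <- function(path) {
  lines <- readLines(path)
  val <- function(key) {
    ln <- grep(paste0("^\\s*", key, ":"), lines, value = TRUE)[1]
    if (is.na(ln)) stop("missing key: ", key)
    trimws(sub(paste0("^\\s*", key, ":"), "", ln))
  }
  nums <- function(key) as.numeric(strsplit(val(key), "\\s+")[[1]])
  N <- as.integer(val("n_states"))
  K <- as.integer(val("n_mixture"))
  delta_mode <- val("delta_mode")
  omega <- nums("omega")
  em <- matrix(0, N, 5)
  for (s in seq_len(N)) {
    at <- grep(paste0("^state ", s, ":"), lines)
    if (!length(at)) stop("missing block for state ", s)
    em[s, ] <- vapply(lines[at + 1:5], function(ln)
      as.numeric(sub(".*:", "", ln)), numeric(1))
  }
  Gamma <- array(0, c(N, N, K))
  for (k in seq_len(K)) {
    at <- grep(paste0("^Gamma ", k, ":"), lines)
    if (!length(at)) stop("missing Gamma block ", k)
    for (i in seq_len(N))
      Gamma[i, , k] <- as.numeric(strsplit(trimws(lines[at + i]), "\\s+")[[1]])
  }
  hmm_params(
    Gamma = Gamma,
    emissions = emission_params(em[, 1], em[, 2], em[, 3], em[, 4], em[, 5]),
    omega = omega,
    delta = if (delta_mode == "estimated") nums("delta") else "stationary"
  )
}
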