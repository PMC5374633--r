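## Multi-start numerical maximum likelihood. The likelihood surface of these
## models is multimodal, so fitting follows the two-stage scheme used in the
## study: draw a large number of random starting parameter sets, evaluate the
## likelihood at each, and pass only the best candidates to a quasi-Newton
## optimizer (nlm) on the unconstrained working scale.

#' Fitting controls
#'
#' Desk-scale defaults (2,000 scanned initial values, 25 optimized starts)
#' keep a fit to seconds while preserving the two-stage procedure; raise
#' `n_initial_scan` (the study's analysis used 100,000) for production runs.
#'
#' @param n_initial_scan random parameter sets scored before optimization.
#' @param n_optimized how many top-ranked candidates are passed to `nlm`.
#' @param max_iterations `nlm` iteration limit per start.
#' @param gradtol `nlm` gradient-norm tolerance on the working scale.
#' @param seed optional RNG seed making scan + fit deterministic.
#' @param n_obs_bic `"dives"` (default) counts observations for BIC as total
#'   dives; `"whales"` counts tag records.
#' @return a list of class `dive_hmm_control`.
#' @export
dive_hmm_control <- function(n_initial_scan = 2000, n_optimized = 25,
                             max_iterations = 500, gradtol = 1e-6,
                             seed = NULL, n_obs_bic = c("dives", "whales")) {
  stopifnot(n_initial_scan >= 1, n_optimized >= 1,
            n_optimized <= n_initial_scan, max_iterations >= 1, gradtol > 0)
  structure(list(n_initial_scan = n_initial_scan, n_optimized = n_optimized,
                 max_iterations = max_iterations, gradtol = gradtol,
                 seed = seed, n_obs_bic = match.arg(n_obs_bic)),
            class = "dive_hmm_control")
}

## One random natural-scale candidate: emission means from jittered data
## quantiles (depth quantiles kept in increasing state order, which biases
## candidates towards the canonical labelling), diagonally dominant
## transition rows, Dirichlet(1) mixture weights.
random_candidate <- function(dives, n_states, n_mixture, delta_mode) {
  N <- n_states
  probs <- (2 * seq_len(N) - 1) / (2 * N)
  jit <- function(n) exp(stats::rnorm(n, 0, 0.4))
  dur <- stats::quantile(dives$duration_min, probs, names = FALSE) * jit(N)
  dep <- sort(stats::quantile(dives$max_depth_m, probs, names = FALSE) *
                jit(N))
  buz <- stats::quantile(dives$n_buzzes, probs, names = FALSE) + 0.05
  em <- emission_params(
    duration_mean = dur, duration_sd = dur * stats::runif(N, 0.3, 0.8),
    depth_mean = dep, depth_sd = dep * stats::runif(N, 0.3, 0.8),
    buzz_rate = buz * jit(N)
  )
  Gamma <- array(0, c(N, N, n_mixture))
  for (k in seq_len(n_mixture)) {
    for (i in seq_len(N)) {
      diag_p <- stats::runif(1, 0.5, 0.9)
      off <- stats::rgamma(N - 1, 1)
      row <- numeric(N)
      row[i] <- diag_p
      row[-i] <- (1 - diag_p) * off / sum(off)
      Gamma[i, , k] <- row
    }
  }
  omega <- if (n_mixture > 1) {
    o <- stats::rgamma(n_mixture, 1); o / sum(o)
  } else 1
  delta <- if (delta_mode == "estimated") rep(1 / N, N) else "stationary"
  hmm_params(Gamma = Gamma, emissions = em, omega = omega, delta = delta)
}

#' Scan random initial values and rank them by likelihood
#'
#' Stage one of the multi-start scheme: draws `n_initial_scan` random
#' parameter sets, evaluates the (mixture) log-likelihood at each, and
#' returns the top `n_optimized`, sorted by decreasing log-likelihood.
#' Deterministic given `control$seed`.
#'
#' @param dives a [dive_table()].
#' @param n_states,n_mixture model dimensions.
#' @param delta_mode `"stationary"` or `"estimated"`.
#' @param control a [dive_hmm_control()].
#' @return list of candidates, each `list(params, loglik)`.
#' @export
scan_initial_values <- function(dives, n_states, n_mixture = 1L,
                                delta_mode = "stationary",
                                control = dive_hmm_control()) {
  dives <- validate_dive_table(as.data.frame(dives))
  if (!is.null(control$seed)) set.seed(control$seed)
  llfn <- make_loglik_fn(dives, n_states, n_mixture)
  cands <- vector("list", control$n_initial_scan)
  lls <- numeric(control$n_initial_scan)
  for (r in seq_len(control$n_initial_scan)) {
    p <- random_candidate(dives, n_states, n_mixture, delta_mode)
    cands[[r]] <- p
    lls[r] <- tryCatch(
      llfn(emission_matrix(p), p$Gamma, p$omega,
           if (delta_mode == "estimated") p$delta else NULL),
      error = function(e) -Inf)
  }
  if (all(!is.finite(lls)))
    stop("no scanned candidate had a finite likelihood; ",
         "check the dive table for degenerate values")
  ord <- order(lls, decreasing = TRUE)[seq_len(control$n_optimized)]
  lapply(ord, function(r) list(params = cands[[r]], loglik = lls[r]))
}

#' Fit a dive-classification hidden Markov model
#'
#' Maximum likelihood fit of the multivariate HMM: per-dive duration and
#' maximum depth are state-dependent Gamma, buzz counts state-dependent
#' Poisson, independent given the hidden state; the state chain is
#' first-order Markov, optionally with a whale-level finite mixture of
#' `n_mixture` transition matrices (discrete random effects). Minimisation of
#' the negative log-likelihood uses [stats::nlm()] on the working scale from
#' each candidate start; the best converged result is kept. Fitted states are
#' reported in canonical order: ascending depth mean, ties broken by
#' duration mean, so state 1 is always the shallowest.
#'
#' @param dives a [dive_table()] covering one or more whales.
#' @param n_states number of hidden states (2-4 in the model catalogue; 1 is
#'   accepted and means iid observations).
#' @param n_mixture number of transition-matrix mixture components (1 = no
#'   random effects).
#' @param delta `"stationary"` (default: each component's initial
#'   distribution is its stationary distribution) or `"estimated"` (adds
#'   N-1 parameters).
#' @param control a [dive_hmm_control()].
#' @param candidates optional pre-scanned candidate list; by default
#'   [scan_initial_values()] is run.
#' @return an object of class `dive_hmm`.
#' @seealso [run_catalogue()], [viterbi()], [predict.dive_hmm()]
#' @export
fit_dive_hmm <- function(dives, n_states, n_mixture = 1L,
                         delta = c("stationary", "estimated"),
                         control = dive_hmm_control(), candidates = NULL) {
  cl <- match.call()
  delta_mode <- match.arg(delta)
  dives <- validate_dive_table(as.data.frame(dives))
  if (is.null(candidates))
    candidates <- scan_initial_values(dives, n_states, n_mixture, delta_mode,
                                      control)
  if (!length(candidates)) stop("no starting candidates supplied")

  llfn <- make_loglik_fn(dives, n_states, n_mixture)
  negll <- function(w) {
    if (!all(is.finite(w))) return(1e10)
    d <- decode_working(w, n_states, n_mixture, delta_mode)
    ll <- tryCatch(llfn(d$em, d$Gamma, d$omega, d$delta),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  best <- NULL
  starts <- data.frame(start = seq_along(candidates),
                       start_loglik = NA_real_, nll = NA_real_,
                       code = NA_integer_, iterations = NA_integer_)
  for (j in seq_along(candidates)) {
    w0 <- natural_to_working(candidates[[j]]$params)
    starts$start_loglik[j] <- candidates[[j]]$loglik
    opt <- tryCatch(
      suppressWarnings(stats::nlm(negll, w0, gradtol = control$gradtol,
                                  iterlim = control$max_iterations)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$minimum) || opt$minimum >= 1e10)
      next                                   # abandoned start
    starts$nll[j] <- opt$minimum
    starts$code[j] <- opt$code
    starts$iterations[j] <- opt$iterations
    if (opt$code <= 2 && (is.null(best) || opt$minimum < best$minimum))
      best <- opt
  }
  if (is.null(best)) {
    # no start converged cleanly; fall back to the best improper one if any
    ok <- which(is.finite(starts$nll))
    if (!length(ok))
      stop("no starting value led to a successful optimization; ",
           "diagnostics: ", nrow(starts), " starts, all abandoned")
    warning("no start met the convergence criterion; returning the best ",
            "non-converged optimum")
    j <- ok[which.min(starts$nll[ok])]
    w0 <- natural_to_working(candidates[[j]]$params)
    best <- suppressWarnings(stats::nlm(negll, w0,
                                        gradtol = control$gradtol,
                                        iterlim = control$max_iterations))
  }
  params <- working_to_natural(best$estimate, n_states, n_mixture, delta_mode)
  params <- canonical_state_order(params)
  n_par <- n_hmm_params(n_states, n_mixture, delta_mode)
  n_obs <- if (control$n_obs_bic == "whales")
    length(unique(dives$whale_id)) else nrow(dives)
  ic <- information_criteria(best$minimum, n_par, n_obs)
  structure(list(
    call = cl,
    n_states = n_states, n_mixture = n_mixture, delta_mode = delta_mode,
    params = params, nll = best$minimum, loglik = -best$minimum,
    n_params = n_par, n_obs = n_obs, aic = ic[["aic"]], bic = ic[["bic"]],
    converged = best$code <= 2, code = best$code,
    iterations = best$iterations, starts = starts,
    seed = control$seed, control = control,
    dives = dives
  ), class = "dive_hmm")
}

#' Reorder states into the canonical labelling
#'
#' States are sorted by ascending depth mean (ties by duration mean), so
#' labels are comparable across fits: state 1 is the shallowest dive type and
#' state N the deepest. The transition matrices, initial distribution and
#' emission table are permuted together, leaving the likelihood unchanged.
#'
#' @param params an [hmm_params] object.
#' @return the relabelled [hmm_params]; attribute `perm` carries the
#'   permutation applied (new index -> old index).
#' @export
canonical_state_order <- function(params) {
  perm <- order(params$emissions$depth_mean, params$emissions$duration_mean)
  em <- params$emissions[perm, ]
  em$state <- seq_len(nrow(em))
  rownames(em) <- NULL
  class(em) <- c("emission_params", "data.frame")
  G <- params$Gamma
  for (k in seq_len(params$n_mixture))
    G[, , k] <- params$Gamma[perm, perm, k]
  out <- hmm_params(Gamma = G, emissions = em, omega = params$omega,
                    delta = if (params$delta_mode == "estimated")
                      params$delta[perm] else "stationary")
  attr(out, "perm") <- perm
  out
}

#' The default ten-model catalogue
#'
#' Three models without random effects (2, 3, 4 states, K = 1) and seven
#' with discrete random effects on the transition matrix: K in {2, 3} for
#' each of 2-4 states, plus a 4-state K = 4 entry.
#'
#' @return a data.frame with columns `n_states`, `n_mixture`.
#' @export
default_catalogue <- function() {
  specs <- rbind(
    expand.grid(n_states = 2:4, n_mixture = 1),
    expand.grid(n_states = 2:4, n_mixture = 2:3),
    data.frame(n_states = 4, n_mixture = 4)
  )
  specs[order(specs$n_mixture, specs$n_states), , drop = FALSE]
}

#' Fit every model in a catalogue
#'
#' @param dives a [dive_table()].
#' @param catalogue a data.frame with `n_states` and `n_mixture` columns
#'   (default [default_catalogue()]).
#' @param control a [dive_hmm_control()]; each spec gets a distinct derived
#'   seed so runs are reproducible.
#' @return a list of `dive_hmm` fits (class `dive_hmm_set`); specs that fail
#'   to fit are recorded as `NULL` with a warning.
#' @export
run_catalogue <- function(dives, catalogue = default_catalogue(),
                          control = dive_hmm_control()) {
  stopifnot(nrow(catalogue) >= 1)
  fits <- vector("list", nrow(catalogue))
  names(fits) <- sprintf("N%d_K%d", catalogue$n_states, catalogue$n_mixture)
  for (i in seq_len(nrow(catalogue))) {
    ctrl <- control
    if (!is.null(control$seed)) ctrl$seed <- control$seed + i
    fits[[i]] <- tryCatch(
      fit_dive_hmm(dives, catalogue$n_states[i], catalogue$n_mixture[i],
                   control = ctrl),
      error = function(e) {
        warning("spec ", names(fits)[i], " failed to fit: ",
                conditionMessage(e))
        NULL
      })
  }
  structure(fits, class = "dive_hmm_set", catalogue = catalogue)
}

#' Select the best model from a set of fits
#'
#' Pure argmin over AIC among the fits that succeeded. When AIC and BIC
#' disagree on the winner the returned fit carries
#' `attr(, "aic_bic_disagree") = TRUE` and a warning is raised.
#'
#' @param fits a `dive_hmm_set` from [run_catalogue()] (or any list of
#'   `dive_hmm` objects).
#' @return the AIC-best `dive_hmm`.
#' @export
select_model <- function(fits) {
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no successful fits to select from")
  fits <- fits[ok]
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  best <- fits[[which.min(aics)]]
  disagree <- which.min(aics) != which.min(bics)
  if (disagree)
    warning("AIC and BIC select different models (AIC: ",
            names(fits)[which.min(aics)], ", BIC: ",
            names(fits)[which.min(bics)], ")")
  attr(best, "aic_bic_disagree") <- disagree
  best
}

#' Model-comparison table for a set of fits
#'
#' @param fits a `dive_hmm_set`.
#' @return data.frame with spec, nll, n_params, AIC, BIC, convergence flag.
#' @export
compare_models <- function(fits) {
  ok <- !vapply(fits, is.null, logical(1))
  out <- data.frame(
    model = names(fits),
    n_states = NA_integer_, n_mixture = NA_integer_, nll = NA_real_,
    n_params = NA_integer_, aic = NA_real_, bic = NA_real_,
    converged = NA
  )
  for (i in which(ok)) {
    f <- fits[[i]]
    out[i, -1] <- list(f$n_states, f$n_mixture, f$nll, f$n_params,
                       f$aic, f$bic, f$converged)
  }
  out
}

#' Repeated-fit numerical stability check
#'
#' Repeats the scan-then-optimize fit `n_runs` times with distinct seeds and
#' reports the spread of the negative log-likelihood, AIC and BIC, plus the
#' fraction of runs whose Viterbi state allocation matches the modal
#' allocation across runs.
#'
#' @param dives a [dive_table()].
#' @param n_states,n_mixture model dimensions.
#' @param control a [dive_hmm_control()]; `control$seed` anchors the run
#'   seeds.
#' @param n_runs number of repeats (>= 2; the study used 100).
#' @return list with `runs` (one row per run: seed, nll, aic, bic,
#'   allocation_agrees), `nll_spread`, and `allocation_agreement` (fraction
#'   of runs matching the modal allocation).
#' @export
stability_check <- function(dives, n_states, n_mixture = 1L,
                            control = dive_hmm_control(), n_runs = 10) {
  stopifnot(n_runs >= 2)
  base_seed <- if (is.null(control$seed)) 1L else control$seed
  fits <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    ctrl <- control
    ctrl$seed <- base_seed + 1000L * r
    fits[[r]] <- fit_dive_hmm(dives, n_states, n_mixture, control = ctrl)
  }
  alloc <- vapply(fits, function(f)
    unlist(lapply(viterbi(f), `[[`, "states"), use.names = FALSE),
    integer(nrow(dives)))
  modal <- apply(alloc, 1, function(s) {
    tab <- tabulate(s, n_states); which.max(tab)
  })
  agrees <- apply(alloc, 2, function(s) all(s == modal))
  runs <- data.frame(
    run = seq_len(n_runs),
    seed = base_seed + 1000L * seq_len(n_runs),
    nll = vapply(fits, `[[`, numeric(1), "nll"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    allocation_agrees = agrees
  )
  list(runs = runs,
       nll_spread = max(runs$nll) - min(runs$nll),
       allocation_agreement = mean(agrees))
}
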