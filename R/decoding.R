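## Viterbi decoding and the state-allocation summaries derived from it.

resolve_params <- function(params) {
  if (inherits(params, "dive_hmm")) params$params
  else validate_hmm_params(params)
}

viterbi_one <- function(ld, Gamma, delta) {
  T_ <- nrow(ld); N <- ncol(ld)
  lG <- log(Gamma)
  phi <- log(delta) + ld[1, ]
  back <- matrix(0L, T_, N)
  if (T_ > 1) {
    for (t in 2:T_) {
      cand <- phi + lG                       # cand[i, j] = phi_i + log G_ij
      back[t, ] <- apply(cand, 2, which.max) # ties -> lowest state index
      phi <- cand[cbind(back[t, ], seq_len(N))] + ld[t, ]
    }
  }
  states <- integer(T_)
  states[T_] <- which.max(phi)
  score <- phi[states[T_]]
  if (T_ > 1)
    for (t in (T_ - 1):1) states[t] <- back[t + 1, states[t + 1]]
  list(states = states, score = score)
}

#' Most likely state sequence per whale (Viterbi algorithm)
#'
#' Exact maximum-probability hidden-state path for each whale's dive
#' sequence, by dynamic programming in log space; ties are broken towards
#' the lower state index. For mixture (random-effects) models each whale is
#' decoded under the component with the highest posterior weight
#' (proportional to \eqn{\omega_k L_w(\Gamma_k)}).
#'
#' @param params a fitted `dive_hmm` or an [hmm_params] object.
#' @param dives a [dive_table()]; defaults to the data the model was fitted
#'   to when `params` is a `dive_hmm`.
#' @return a named list (one element per whale) of
#'   `list(whale_id, states, component, score)`, where `score` is the decoded
#'   path's log-probability (including emissions).
#' @export
viterbi <- function(params, dives = NULL) {
  if (is.null(dives) && inherits(params, "dive_hmm")) dives <- params$dives
  params <- resolve_params(params)
  dives <- validate_dive_table(as.data.frame(dives))
  if (nrow(dives) == 0) stop("empty dive table")
  N <- params$n_states; K <- params$n_mixture
  ld <- state_logdensity(dives$duration_min, dives$max_depth_m,
                         dives$n_buzzes, params$emissions)
  Gk <- lapply(seq_len(K), function(k) matrix(params$Gamma[, , k], N, N))
  dk <- lapply(seq_len(K), function(k) component_delta(params, k))
  idx <- split_by_whale(dives)
  out <- lapply(names(idx), function(w) {
    ldw <- ld[idx[[w]], , drop = FALSE]
    k <- if (K == 1) 1L else {
      lls <- vapply(seq_len(K), function(k)
        forward_loglik_cpp(ldw, Gk[[k]], dk[[k]]), numeric(1))
      which.max(log(params$omega) + lls)
    }
    v <- viterbi_one(ldw, Gk[[k]], dk[[k]])
    list(whale_id = w, states = v$states, component = k, score = v$score)
  })
  names(out) <- names(idx)
  out
}

#' Per-whale, per-state dive counts
#'
#' @param dives a [dive_table()].
#' @param states integer state labels aligned to the rows of `dives` (e.g.
#'   `unlist` of a [viterbi()] decoding).
#' @param n_states number of states.
#' @return a whales x states count matrix (rows in order of first
#'   appearance).
#' @export
state_counts <- function(dives, states, n_states = max(states)) {
  stopifnot(length(states) == nrow(dives))
  idx <- split_by_whale(dives)
  t(vapply(idx, function(i) tabulate(states[i], n_states),
           integer(n_states)))
}

#' Allocation summaries from a whale-by-state count matrix
#'
#' @param counts a whales x states matrix of dive counts per state.
#' @return list with `totals` (dives per state), `whale_counts` (whales
#'   showing each state at least once), `states_histogram` (whales by number
#'   of distinct states shown, 1..N), and `counts` itself.
#' @export
allocation_summary <- function(counts) {
  counts <- as.matrix(counts)
  N <- ncol(counts)
  list(totals = colSums(counts),
       whale_counts = colSums(counts > 0),
       states_histogram = tabulate(rowSums(counts > 0), N),
       counts = counts)
}

#' Decode and summarise the state allocation of every whale
#'
#' @inheritParams viterbi
#' @return the [allocation_summary()] list, plus `sequences` (the [viterbi()]
#'   decoding) and `states` (labels aligned to dive-table rows).
#' @export
allocate_states <- function(params, dives = NULL) {
  if (is.null(dives) && inherits(params, "dive_hmm")) dives <- params$dives
  seqs <- viterbi(params, dives)
  states <- unlist(lapply(seqs, `[[`, "states"), use.names = FALSE)
  n_states <- resolve_params(params)$n_states
  out <- allocation_summary(state_counts(dives, states, n_states))
  out$sequences <- seqs
  out$states <- states
  out
}

#' Per-whale state-frequency summaries
#'
#' For each whale the proportion of its dives in each state, summarised over
#' whales by mean, median and interquartile range, with the even-appearance
#' reference 1/N for comparison. Whales with zero dives are excluded with a
#' warning.
#'
#' @param counts a whales x states dive-count matrix (from [state_counts()]
#'   or [allocation_summary()]).
#' @return data.frame with one row per state: `mean`, `median`, `q25`, `q75`,
#'   and the `even` reference.
#' @export
state_proportions <- function(counts) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " whale(s) with zero dives excluded")
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (!nrow(counts)) stop("no whales with dives")
  prop <- counts / tot
  data.frame(
    state = seq_len(ncol(counts)),
    mean = colMeans(prop),
    median = apply(prop, 2, stats::median),
    q25 = apply(prop, 2, stats::quantile, 0.25, names = FALSE),
    q75 = apply(prop, 2, stats::quantile, 0.75, names = FALSE),
    even = 1 / ncol(counts)
  )
}

#' Persistence-versus-switching summary
#'
#' Contrasts the fitted transition matrix's diagonal (state persistence) with
#' its off-diagonal entries (state switching), tabulates decoded transition
#' counts, and reports the decoded run lengths (bout lengths) per state. A
#' state is flagged persistent when its diagonal entry exceeds every
#' off-diagonal entry in its row.
#'
#' @param sequences a [viterbi()] decoding.
#' @param params the fitted `dive_hmm` or [hmm_params] (component 1 is
#'   reported for mixture models).
#' @return list with `transition_matrix`, `persistence` (per-state logical),
#'   `decoded_counts` (N x N transition count matrix), `run_lengths` (list of
#'   decoded bout lengths per state), and `mean_run_length`.
#' @export
bout_summary <- function(sequences, params) {
  params <- resolve_params(params)
  N <- params$n_states
  G <- matrix(params$Gamma[, , 1], N, N)
  persistence <- vapply(seq_len(N), function(i)
    G[i, i] > max(G[i, -i]), logical(1))
  counts <- matrix(0L, N, N)
  run_lengths <- rep(list(integer(0)), N)
  for (sq in sequences) {
    s <- sq$states
    if (length(s) > 1)
      for (t in seq_len(length(s) - 1))
        counts[s[t], s[t + 1]] <- counts[s[t], s[t + 1]] + 1L
    r <- rle(s)
    for (j in seq_len(N))
      run_lengths[[j]] <- c(run_lengths[[j]], r$lengths[r$values == j])
  }
  list(transition_matrix = G,
       persistence = persistence,
       decoded_counts = counts,
       run_lengths = run_lengths,
       mean_run_length = vapply(run_lengths, function(x)
         if (length(x)) mean(x) else NA_real_, numeric(1)))
}
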