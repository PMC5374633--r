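## Synthetic study generator. Emulates a 20-whale DTAG study of short-finned
## pilot whales off Cape Hatteras: heterogeneous record lengths (2-64 dives
## per whale), first-order Markov dynamics between four dive states, and
## Gamma/Gamma/Poisson observations per dive. Ground-truth state labels are
## kept so that fitting and decoding can be audited.

## Per-whale total dive counts of the 20 tag deployments; the default study
## design resamples from these.
STUDY_DIVE_COUNTS <- c(4, 9, 7, 3, 17, 5, 2, 3, 34, 34,
                       3, 4, 32, 64, 7, 7, 3, 9, 10, 2)

#' Default generating parameters for the synthetic study
#'
#' A 4-state model anchored to the fitted study values: the transition matrix
#' of the four dive states (rows renormalised to sum exactly to 1), state
#' medians of 3.33 min / 27 m for the shallow non-foraging state and
#' 9.6 min / 171 m for the common intermediate state, and per-state mean buzz
#' counts (0.07, 11.65, 2, 30.45). Quantities the study does not report are
#' package defaults: every Gamma sd is half its mean (cv = 0.5), and the two
#' unanchored states use depth means of 90 m and 600 m with duration means of
#' 7 and 16 min, chosen so that state depth means increase with the state
#' index (the package's canonical state order).
#'
#' @return an [hmm_params] object with `delta = "stationary"`.
#' @export
default_hmm_params <- function() {
  Gamma <- matrix(c(
    0.526, 0.168, 0.275, 0.030,
    0.040, 0.714, 0.134, 0.112,
    0.142, 0.087, 0.730, 0.041,
    0.069, 0.148, 0.140, 0.643
  ), 4, 4, byrow = TRUE)
  Gamma <- Gamma / rowSums(Gamma)
  dur_mean <- c(gamma_mean_from_median(3.33), 7,
                gamma_mean_from_median(9.6), 16)
  dep_mean <- c(gamma_mean_from_median(27), 90,
                gamma_mean_from_median(171), 600)
  em <- emission_params(
    duration_mean = dur_mean, duration_sd = 0.5 * dur_mean,
    depth_mean = dep_mean, depth_sd = 0.5 * dep_mean,
    buzz_rate = c(0.07, 11.65, 2, 30.45)
  )
  hmm_params(Gamma = Gamma, emissions = em, delta = "stationary")
}

#' Simulate one whale's dive sequence
#'
#' Draws a mixture component by `omega`, the first state from the initial
#' distribution, subsequent states from the component's transition matrix,
#' and observations from the state's Gamma/Gamma/Poisson emissions. Depth
#' draws below the dive threshold are rejected and redrawn (such submergences
#' would not enter a dive table); the number of redraws is recorded in the
#' `n_depth_redraws` attribute.
#'
#' @param params an [hmm_params] object.
#' @param n_dives number of dives to simulate.
#' @param whale_id identifier for the simulated record.
#' @param threshold dive depth threshold (m).
#' @param gap_mean_min mean surface gap between dives (minutes, exponential).
#' @return a [dive_table()] with attributes `states` (true labels),
#'   `component` (mixture component drawn) and `n_depth_redraws`.
#' @export
simulate_whale <- function(params, n_dives, whale_id = "w1", threshold = 20,
                           gap_mean_min = 15) {
  params <- validate_hmm_params(params)
  N <- params$n_states
  k <- sample.int(params$n_mixture, 1, prob = params$omega)
  G <- matrix(params$Gamma[, , k], N, N)
  delta <- component_delta(params, k)
  states <- integer(n_dives)
  states[1] <- sample.int(N, 1, prob = delta)
  for (t in seq_len(n_dives)[-1])
    states[t] <- sample.int(N, 1, prob = G[states[t - 1], ])
  em <- params$emissions
  gd <- gamma_shape_scale(em$duration_mean, em$duration_sd)
  gz <- gamma_shape_scale(em$depth_mean, em$depth_sd)
  duration <- stats::rgamma(n_dives, shape = gd$shape[states],
                            scale = gd$scale[states])
  depth <- stats::rgamma(n_dives, shape = gz$shape[states],
                         scale = gz$scale[states])
  redraws <- 0L
  repeat {
    shallow <- which(depth < threshold)
    if (!length(shallow)) break
    redraws <- redraws + length(shallow)
    depth[shallow] <- stats::rgamma(length(shallow),
                                    shape = gz$shape[states[shallow]],
                                    scale = gz$scale[states[shallow]])
  }
  buzzes <- stats::rpois(n_dives, em$buzz_rate[states])
  gaps <- stats::rexp(n_dives, rate = 1 / (gap_mean_min * 60))
  start_s <- cumsum(gaps) + c(0, cumsum(duration * 60))[seq_len(n_dives)]
  x <- dive_table(rep(whale_id, n_dives), start_s, start_s + duration * 60,
                  duration, depth, buzzes, threshold = threshold)
  attr(x, "states") <- states
  attr(x, "component") <- k
  attr(x, "n_depth_redraws") <- redraws
  x
}

#' Simulate a whole tagging study
#'
#' @param n_whales number of whales (default 20).
#' @param dive_counts per-whale dive counts; by default resampled with
#'   replacement from the study's 20 deployment totals (2-64 dives).
#' @param params generating parameters, default [default_hmm_params()].
#' @param gap_mean_min mean surface gap between dives (minutes).
#' @param seed optional RNG seed for reproducibility.
#' @return list with `dives` (one [dive_table()] for all whales), `states`
#'   (ground-truth labels aligned to rows), `components` (per-whale mixture
#'   component), and `records` (per-whale `whale_id`, `record_h` in hours —
#'   dive time plus surface gaps, including a leading and trailing gap).
#' @export
simulate_study <- function(n_whales = 20, dive_counts = NULL,
                           params = default_hmm_params(),
                           gap_mean_min = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dive_counts))
    dive_counts <- sample(STUDY_DIVE_COUNTS, n_whales, replace = TRUE)
  stopifnot(length(dive_counts) == n_whales, all(dive_counts >= 1))
  ids <- sprintf("gm%02d", seq_len(n_whales))
  whales <- lapply(seq_len(n_whales), function(i)
    simulate_whale(params, dive_counts[i], whale_id = ids[i],
                   gap_mean_min = gap_mean_min))
  dives <- do.call(rbind, whales)
  dives <- validate_dive_table(as.data.frame(dives))
  records <- data.frame(
    whale_id = ids,
    record_h = vapply(whales, function(w)
      (max(w$end_s) + stats::rexp(1, 1 / (gap_mean_min * 60))) / 3600,
      numeric(1))
  )
  list(dives = dives,
       states = unlist(lapply(whales, attr, "states"), use.names = FALSE),
       components = vapply(whales, attr, integer(1), "component"),
       records = records)
}

#' Render a whale's dive table as a depth profile
#'
#' Produces a regularly sampled depth series with one piecewise-linear
#' V-shaped excursion per dive and surface (0 m) in between, plus buzz event
#' times placed uniformly inside each dive. Dive start/end times are snapped
#' to the sample grid; the snapped dive table is returned so that
#' segmentation and summarisation recover every (duration, max depth, buzz
#' count) triple exactly. The samples at the snapped boundaries sit just
#' below the threshold, matching the segmentation boundary rule.
#'
#' @param dives a [dive_table()] for a single whale.
#' @param sampling_hz sampling rate (default 5).
#' @param threshold dive threshold (m).
#' @return list with `time_s`, `depth_m`, `buzz_times`, and `dives` (the
#'   grid-snapped table the profile actually encodes).
#' @export
render_depth_profile <- function(dives, sampling_hz = 5, threshold = 20) {
  stopifnot(length(unique(dives$whale_id)) <= 1)
  dt <- 1 / sampling_hz
  end_time <- if (nrow(dives)) max(dives$end_s) + 60 else 60
  time_s <- seq(0, end_time, by = dt)
  depth <- numeric(length(time_s))
  buzz_times <- numeric(0)
  snap <- function(t) round(t / dt) * dt
  out <- dives
  prev_i1 <- -1L
  for (i in seq_len(nrow(dives))) {
    s <- snap(dives$start_s[i])
    e <- snap(dives$end_s[i])
    if (e - s < 4 * dt) e <- s + 4 * dt      # need room for an interior peak
    i0 <- round(s / dt) + 1L
    if (i0 <= prev_i1 + 1L) {                # keep a surface sample between dives
      i0 <- prev_i1 + 2L
      s <- (i0 - 1L) * dt
      if (round(e / dt) + 1L - i0 < 4L) e <- s + 4 * dt
    }
    i1 <- round(e / dt) + 1L
    prev_i1 <- i1
    ip <- round((i0 + i1) / 2)
    # boundary samples just below threshold; interior >= threshold, peak exact
    depth[i0] <- threshold - 1
    depth[i1] <- threshold - 1
    depth[ip] <- dives$max_depth_m[i]
    if (ip > i0 + 1L) {
      j <- (i0 + 1L):(ip - 1L)
      depth[j] <- threshold + (dives$max_depth_m[i] - threshold) *
        (j - i0) / (ip - i0)
    }
    if (i1 > ip + 1L) {
      j <- (ip + 1L):(i1 - 1L)
      depth[j] <- threshold + (dives$max_depth_m[i] - threshold) *
        (i1 - j) / (i1 - ip)
    }
    out$start_s[i] <- s
    out$end_s[i] <- e
    out$duration_min[i] <- (e - s) / 60
    if (dives$n_buzzes[i] > 0)
      buzz_times <- c(buzz_times,
                      sort(stats::runif(dives$n_buzzes[i],
                                        min = s + dt, max = e - dt)))
  }
  list(time_s = time_s, depth_m = depth, buzz_times = buzz_times,
       dives = validate_dive_table(as.data.frame(out)))
}
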