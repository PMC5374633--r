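## Time budgets, tag-duration regressions, and the noncentral-F power
## computations used to qualify them.

#' Per-whale time budget
#'
#' Splits one whale's record duration into surface time (shallower than the
#' dive threshold) and time in each decoded dive state: state hours are the
#' sum of the durations of the dives labelled with that state, surface hours
#' the remainder of the record (minus any excluded time).
#'
#' @param dives a [dive_table()] for one whale.
#' @param states decoded state labels aligned to `dives` rows.
#' @param record_h total record duration in hours.
#' @param n_states number of states.
#' @param excluded_h hours excluded from analysis (e.g. incomplete dives).
#' @return one-row data.frame: `record_h`, `surface_h`, `state<j>_h`,
#'   `surface_prop`, `state<j>_prop`.
#' @export
time_budget <- function(dives, states, record_h, n_states,
                        excluded_h = 0) {
  if (length(states) != nrow(dives))
    stop("state sequence is not aligned to the dive table")
  dive_h <- vapply(seq_len(n_states), function(j)
    sum(dives$duration_min[states == j]) / 60, numeric(1))
  surface_h <- record_h - sum(dive_h) - excluded_h
  if (surface_h < -1e-8)
    stop("dive time exceeds the record duration")
  out <- data.frame(record_h = record_h, surface_h = surface_h)
  for (j in seq_len(n_states)) out[[paste0("state", j, "_h")]] <- dive_h[j]
  out$surface_prop <- surface_h / record_h
  for (j in seq_len(n_states))
    out[[paste0("state", j, "_prop")]] <- dive_h[j] / record_h
  out
}

#' Time budgets for every whale in a study
#'
#' @param dives a [dive_table()].
#' @param states decoded labels aligned to `dives` rows.
#' @param records data.frame with `whale_id` and `record_h` (hours); whales
#'   with no dives get a fully-surface budget.
#' @param n_states number of states.
#' @return data.frame with one row per whale (in `records` order).
#' @export
study_time_budgets <- function(dives, states, records, n_states) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    w <- records$whale_id[i]
    sel <- dives$whale_id == w
    b <- time_budget(dives[sel, , drop = FALSE], states[sel],
                     records$record_h[i], n_states)
    cbind(data.frame(whale_id = w), b)
  })
  do.call(rbind, rows)
}

ols_report <- function(fit) {
  sm <- summary(fit)
  fs <- sm$fstatistic
  list(r_squared = sm$r.squared,
       f = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
       p = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       fit = fit)
}

#' Regression of tag duration on surface-time proportion
#'
#' Ordinary least squares with tag-record duration (hours) as the response
#' and the proportion of time at the surface as the predictor, with the
#' classical overall F test.
#'
#' @param record_h tag durations (hours), one per whale.
#' @param surface_prop per-whale surface proportions.
#' @return list with `r_squared`, `f`, `df1`, `df2`, `p` and the `lm` fit.
#' @export
surface_regression <- function(record_h, surface_prop) {
  stopifnot(length(record_h) == length(surface_prop))
  if (length(record_h) < 3) stop("need at least 3 whales")
  if (stats::var(surface_prop) == 0)
    stop("surface proportion has zero variance")
  ols_report(stats::lm(record_h ~ surface_prop))
}

#' Regression of tag duration on the number of states shown
#'
#' Least squares of tag duration on indicator variables for the number of
#' distinct states a whale displayed, with one state as the reference level;
#' the overall F has (g - 1, n - g) degrees of freedom for g non-empty
#' groups. Groups with no whales are dropped with a warning.
#'
#' @param record_h tag durations (hours), one per whale.
#' @param n_states_shown per-whale number of distinct states (e.g.
#'   `rowSums(counts > 0)`).
#' @return list with `r_squared`, `f`, `df1`, `df2`, `p`, `group_means` and
#'   the `lm` fit.
#' @export
states_regression <- function(record_h, n_states_shown) {
  stopifnot(length(record_h) == length(n_states_shown))
  lev <- sort(unique(n_states_shown))
  missing_groups <- setdiff(seq_len(max(n_states_shown)), lev)
  if (length(missing_groups))
    warning("no whales with ", paste(missing_groups, collapse = ", "),
            " state(s); group(s) dropped")
  if (length(lev) < 2) stop("need at least 2 state-count groups")
  g <- factor(n_states_shown, levels = lev)   # reference = fewest states
  rep <- ols_report(stats::lm(record_h ~ g))
  rep$group_means <- tapply(record_h, g, mean)
  rep
}

#' Power of a fixed-effects regression F test
#'
#' Computes \eqn{P(F'(u, v, \lambda) > F_{1-\alpha;u,v})} with noncentrality
#' \eqn{\lambda = f^2 (u + v + 1)}, the convention of the classical power
#' package for linear-model effect sizes (Cohen's \eqn{f^2}). Note other
#' texts use \eqn{\lambda = f^2 (v + 1)}.
#'
#' @param u numerator degrees of freedom.
#' @param v denominator degrees of freedom.
#' @param f2 effect size \eqn{f^2 = R^2 / (1 - R^2)}.
#' @param alpha significance level.
#' @return the power (a probability).
#' @export
regression_power <- function(u, v, f2, alpha = 0.05) {
  stopifnot(u >= 1, v >= 1, f2 >= 0, alpha > 0, alpha < 1)
  crit <- stats::qf(1 - alpha, u, v)
  stats::pf(crit, u, v, ncp = f2 * (u + v + 1), lower.tail = FALSE)
}
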