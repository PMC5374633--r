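## Standard modelling-object methods for `dive_hmm` fits.

#' @export
print.dive_hmm <- function(x, digits = 3, ...) {
  cat("Dive-classification hidden Markov model\n")
  cat(sprintf("  %d states, %d mixture component%s, initial distribution: %s\n",
              x$n_states, x$n_mixture, if (x$n_mixture > 1) "s" else "",
              x$delta_mode))
  cat(sprintf("  log-likelihood %.3f on %d parameters (%d dives, %d whales)\n",
              x$loglik, x$n_params, nrow(x$dives),
              length(unique(x$dives$whale_id))))
  cat(sprintf("  AIC %.2f   BIC %.2f   converged: %s\n",
              x$aic, x$bic, x$converged))
  invisible(x)
}

#' @export
summary.dive_hmm <- function(object, digits = 3, ...) {
  out <- list(model = object,
              emissions = object$params$emissions,
              Gamma = object$params$Gamma,
              omega = object$params$omega,
              delta = t(vapply(seq_len(object$n_mixture), function(k)
                component_delta(object$params, k),
                numeric(object$n_states))))
  class(out) <- "summary.dive_hmm"
  out
}

#' @export
print.summary.dive_hmm <- function(x, digits = 3, ...) {
  print(x$model)
  cat("\nState-dependent distributions (duration Gamma [min], depth Gamma",
      "[m], buzzes Poisson):\n")
  print(format(x$emissions, digits = digits), row.names = FALSE)
  for (k in seq_len(dim(x$Gamma)[3])) {
    if (dim(x$Gamma)[3] > 1)
      cat(sprintf("\nTransition matrix, component %d (weight %.3f):\n",
                  k, x$omega[k]))
    else cat("\nTransition matrix:\n")
    G <- matrix(x$Gamma[, , k], nrow(x$emissions))
    dimnames(G) <- list(paste0("from_", seq_len(nrow(G))),
                        paste0("to_", seq_len(nrow(G))))
    print(round(G, digits))
  }
  cat("\nInitial distribution (per component):\n")
  print(round(x$delta, digits))
  invisible(x)
}

#' @export
coef.dive_hmm <- function(object, ...) {
  list(emissions = object$params$emissions,
       Gamma = object$params$Gamma,
       omega = object$params$omega,
       delta = t(vapply(seq_len(object$n_mixture), function(k)
         component_delta(object$params, k), numeric(object$n_states))))
}

#' @export
logLik.dive_hmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Decode dive states from a fitted model
#'
#' `predict()` on a `dive_hmm` returns the Viterbi state labels, aligned to
#' the rows of the dive table.
#'
#' @param object a fitted `dive_hmm`.
#' @param newdata an optional [dive_table()]; defaults to the fitted data.
#' @param ... unused.
#' @return an integer vector of state labels.
#' @export
predict.dive_hmm <- function(object, newdata = NULL, ...) {
  seqs <- viterbi(object, dives = newdata)
  unlist(lapply(seqs, `[[`, "states"), use.names = FALSE)
}

#' Simulate dive tables from a fitted model
#'
#' @param object a fitted `dive_hmm`.
#' @param nsim number of studies to simulate.
#' @param seed optional RNG seed.
#' @param n_whales,dive_counts study design passed to [simulate_study()];
#'   defaults mirror the fitted data's whales and dive counts.
#' @param ... unused.
#' @return a list of `nsim` [simulate_study()] results.
#' @export
simulate.dive_hmm <- function(object, nsim = 1, seed = NULL,
                              n_whales = NULL, dive_counts = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dive_counts))
    dive_counts <- as.integer(table(factor(object$dives$whale_id,
                                           levels = unique(object$dives$whale_id))))
  if (is.null(n_whales)) n_whales <- length(dive_counts)
  lapply(seq_len(nsim), function(i)
    simulate_study(n_whales = n_whales, dive_counts = dive_counts,
                   params = object$params))
}

#' Plot fitted state-dependent distributions over the data
#'
#' One panel per observed variable: histograms of the pooled observations
#' with the fitted per-state densities (weighted by the decoded state
#' frequencies) overlaid.
#'
#' @param x a fitted `dive_hmm`.
#' @param which subset of `c("duration", "depth", "buzzes")`.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.dive_hmm <- function(x, which = c("duration", "depth", "buzzes"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  em <- x$params$emissions
  N <- x$n_states
  states <- predict(x)
  wts <- tabulate(states, N) / length(states)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  cols <- c("red", "blue", "darkgreen", "purple")[seq_len(N)]
  panels <- list(
    duration = list(v = x$dives$duration_min, lab = "Dive duration (min)",
                    dens = function(g, e) {
                      p <- gamma_shape_scale(e$duration_mean, e$duration_sd)
                      stats::dgamma(g, shape = p$shape, scale = p$scale)
                    }),
    depth = list(v = x$dives$max_depth_m, lab = "Maximum depth (m)",
                 dens = function(g, e) {
                   p <- gamma_shape_scale(e$depth_mean, e$depth_sd)
                   stats::dgamma(g, shape = p$shape, scale = p$scale)
                 }),
    buzzes = list(v = x$dives$n_buzzes, lab = "Buzzes per dive",
                  dens = function(g, e) stats::dpois(round(g), e$buzz_rate))
  )
  for (nm in which) {
    pn <- panels[[nm]]
    graphics::hist(pn$v, freq = FALSE, main = "", xlab = pn$lab,
                   col = "grey90", border = "grey70", ...)
    g <- seq(max(min(pn$v), 1e-3), max(pn$v), length.out = 300)
    for (j in seq_len(N))
      graphics::lines(g, wts[j] * pn$dens(g, em[j, ]), col = cols[j],
                      lwd = 2)
    graphics::legend("topright", legend = paste("state", seq_len(N)),
                     col = cols, lwd = 2, bty = "n")
  }
  invisible(x)
}
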