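## In-study summary tables shipped with the package: the per-deployment
## tagging summary (with per-state dive allocations) and the fitted 4x4
## transition matrix. Both are validated against their published invariants
## at load time.

#' Load a study fixture table
#'
#' `"table1"` is the tagging summary: one row per deployment with tag id,
#' on/off times, total record time (hh:mm, also parsed to decimal hours as
#' `total_h`), sex, total dives and the number of dives allocated to each of
#' the four states. `"table2"` is the fitted transition-probability matrix
#' with per-state dive counts; `attr(, "Gamma")` holds the 4x4 matrix with
#' rows renormalised to sum exactly to 1.
#'
#' Invariants checked at load: 20 whales; per-row state allocations summing
#' to the row's total dives; 259 dives in total; 124 h 06 m of recording;
#' transition rows summing to 1 within printed rounding (0.005).
#'
#' @param name `"table1"` or `"table2"`.
#' @return a data.frame (see above).
#' @export
load_dive_fixture <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      switch(name,
                             table1 = "table1_tagging_summary.csv",
                             table2 = "table2_transition_matrix.csv"),
                      package = "diveHMM", mustWork = TRUE)
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (name == "table1") {
    hm <- do.call(rbind, strsplit(x$total_time, ":", fixed = TRUE))
    x$total_h <- as.numeric(hm[, 1]) + as.numeric(hm[, 2]) / 60
    states <- as.matrix(x[c("state1", "state2", "state3", "state4")])
    if (nrow(x) != 20)
      stop("fixture corrupt: expected 20 deployments")
    if (any(rowSums(states) != x$total_dives))
      stop("fixture corrupt: state allocations do not sum to total dives")
    if (sum(x$total_dives) != 259)
      stop("fixture corrupt: grand total must be 259 dives")
    if (abs(sum(x$total_h) - (124 + 6 / 60)) > 1e-9)
      stop("fixture corrupt: total recording time must be 124 h 06 m")
  } else {
    G <- as.matrix(x[paste0("to_state", 1:4)])
    if (any(abs(rowSums(G) - 1) > 0.005))
      stop("fixture corrupt: transition rows must sum to 1 within rounding")
    if (sum(x$n_dives) != 259)
      stop("fixture corrupt: state dive counts must sum to 259")
    attr(x, "Gamma") <- unname(G / rowSums(G))
  }
  x
}
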