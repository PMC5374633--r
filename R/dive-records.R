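## Dive records: segmentation of depth time series into dives and the dive
## table that everything downstream consumes. A dive is any submergence
## reaching 20 m or deeper; depth shallower than 20 m is surface time. Each
## dive contributes one observation triple: duration (min), maximum depth (m),
## buzz count.

DIVE_TABLE_COLS <- c("whale_id", "start_s", "end_s", "duration_min",
                     "max_depth_m", "n_buzzes")

#' Construct a validated dive table
#'
#' The dive table is the package's central container: one row per dive,
#' grouped by whale in time order. Durations are minutes, depths meters
#' (positive down), times seconds since tag-on.
#'
#' @param whale_id whale identifiers.
#' @param start_s,end_s dive start/end, seconds since tag-on.
#' @param duration_min dive duration in minutes.
#' @param max_depth_m maximum depth (>= the 20 m dive threshold).
#' @param n_buzzes buzz count per dive, non-negative integer.
#' @param threshold dive depth threshold used for validation (m).
#' @return a data.frame of class `dive_table`.
#' @export
dive_table <- function(whale_id, start_s, end_s, duration_min, max_depth_m,
                       n_buzzes, threshold = 20) {
  x <- data.frame(whale_id = as.character(whale_id), start_s = start_s,
                  end_s = end_s, duration_min = duration_min,
                  max_depth_m = max_depth_m, n_buzzes = n_buzzes)
  validate_dive_table(x, threshold = threshold)
}

validate_dive_table <- function(x, threshold = 20) {
  miss <- setdiff(DIVE_TABLE_COLS, names(x))
  if (length(miss))
    stop("dive table is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(
    x$duration_min <= 0 | x$max_depth_m < threshold |
      x$n_buzzes < 0 | x$n_buzzes != round(x$n_buzzes) |
      abs((x$end_s - x$start_s) / 60 - x$duration_min) > 0.02
  )
  if (length(bad))
    stop("invalid dive rows (duration/depth/buzz/timing): ",
         paste(bad, collapse = ", "))
  for (w in unique(x$whale_id)) {
    xi <- x[x$whale_id == w, ]
    if (is.unsorted(xi$start_s))
      stop("dives for whale ", w, " are not in time order")
    if (nrow(xi) > 1 && any(xi$start_s[-1] < xi$end_s[-nrow(xi)]))
      stop("overlapping dives for whale ", w)
  }
  class(x) <- unique(c("dive_table", class(x)))
  x
}

#' Segment a depth record into dives
#'
#' Finds maximal submergences reaching `threshold` or deeper. Boundaries
#' follow a reproducible rule: the dive starts at the last sample shallower
#' than the threshold before the descent and ends at the first sample
#' shallower than the threshold after the ascent. Spans truncated by the
#' record's start or end are flagged incomplete.
#'
#' @param time_s strictly increasing, regularly spaced sample times (s).
#' @param depth_m non-negative depths (m), same length.
#' @param threshold dive threshold in meters (default 20).
#' @param min_duration_s drop dives shorter than this (default 0: none).
#' @param hysteresis_m merge submergences separated by excursions that stay
#'   within this margin below the threshold (default 0: none).
#' @return data.frame with columns `start_s`, `end_s`, `incomplete`.
#' @export
segment_dives <- function(time_s, depth_m, threshold = 20,
                          min_duration_s = 0, hysteresis_m = 0) {
  if (length(time_s) == 0) stop("empty depth series")
  if (length(time_s) != length(depth_m))
    stop("time and depth vectors must have equal length")
  if (any(diff(time_s) <= 0)) stop("sample times must be strictly increasing")
  deep <- depth_m >= threshold
  r <- rle(deep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i0 <- starts[r$values]
  i1 <- ends[r$values]
  if (!length(i0))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      incomplete = logical(0)))
  if (hysteresis_m > 0 && length(i0) > 1) {
    keep <- rep(TRUE, length(i0))
    for (j in seq_len(length(i0) - 1)) {
      gap <- depth_m[(i1[j] + 1L):(i0[j + 1L] - 1L)]
      if (min(gap) >= threshold - hysteresis_m) {
        i1[j + 1L] <- i1[j + 1L]
        i0[j + 1L] <- i0[j]
        keep[j] <- FALSE
      }
    }
    i0 <- i0[keep]; i1 <- i1[keep]
  }
  incomplete <- (i0 == 1L) | (i1 == length(depth_m))
  start_s <- ifelse(i0 == 1L, time_s[1L], time_s[pmax(i0 - 1L, 1L)])
  end_s <- ifelse(i1 == length(depth_m), time_s[length(time_s)],
                  time_s[pmin(i1 + 1L, length(time_s))])
  out <- data.frame(start_s = start_s, end_s = end_s, incomplete = incomplete)
  if (min_duration_s > 0)
    out <- out[out$end_s - out$start_s >= min_duration_s | out$incomplete, ]
  rownames(out) <- NULL
  out
}

#' Summarise one segmented dive
#'
#' Computes the observation triple for a dive interval: duration in minutes,
#' the maximum depth attained inside the closed interval, and the number of
#' buzz events falling inside the closed interval (boundary ties counted).
#' Incomplete intervals (tag detached mid-dive) are refused.
#'
#' @param time_s,depth_m the depth record the interval was segmented from.
#' @param interval a one-row data.frame from [segment_dives()].
#' @param buzz_times buzz event times (s), may be empty.
#' @return one-row data.frame with `start_s`, `end_s`, `duration_min`,
#'   `max_depth_m`, `n_buzzes`.
#' @export
summarize_dive <- function(time_s, depth_m, interval, buzz_times = numeric()) {
  if (isTRUE(interval$incomplete))
    stop("refusing to summarise an incomplete dive (tag detached mid-dive)")
  inside <- time_s >= interval$start_s & time_s <= interval$end_s
  data.frame(
    start_s = interval$start_s, end_s = interval$end_s,
    duration_min = (interval$end_s - interval$start_s) / 60,
    max_depth_m = max(depth_m[inside]),
    n_buzzes = sum(buzz_times >= interval$start_s &
                     buzz_times <= interval$end_s)
  )
}

#' Derive a dive table from a depth record
#'
#' Convenience wrapper: segment, drop incomplete dives, summarise each.
#'
#' @inheritParams segment_dives
#' @param buzz_times buzz event times (s).
#' @param whale_id identifier for the record.
#' @return a [dive_table()] (possibly with zero rows).
#' @export
dives_from_profile <- function(time_s, depth_m, buzz_times = numeric(),
                               whale_id = "w1", threshold = 20, ...) {
  seg <- segment_dives(time_s, depth_m, threshold = threshold, ...)
  seg <- seg[!seg$incomplete, , drop = FALSE]
  if (!nrow(seg))
    return(dive_table(character(0), numeric(0), numeric(0), numeric(0),
                      numeric(0), integer(0), threshold = threshold))
  rows <- lapply(seq_len(nrow(seg)), function(i)
    summarize_dive(time_s, depth_m, seg[i, ], buzz_times))
  x <- do.call(rbind, rows)
  dive_table(rep(whale_id, nrow(x)), x$start_s, x$end_s, x$duration_min,
             x$max_depth_m, x$n_buzzes, threshold = threshold)
}

#' Read and write dive tables as comma-separated text
#'
#' Column layout: `whale_id, start_s, end_s, duration_min, max_depth_m,
#' n_buzzes`. The round trip is lossless; rows are grouped by whale in time
#' order and validated on read.
#'
#' @param path file path.
#' @param x a dive table.
#' @return `read_dive_table()` a validated `dive_table`;
#'   `write_dive_table()` `path`, invisibly.
#' @export
read_dive_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(DIVE_TABLE_COLS, names(x))
  if (length(miss))
    stop("dive table at ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  validate_dive_table(x)
}

#' @rdname read_dive_table
#' @export
write_dive_table <- function(x, path) {
  x <- validate_dive_table(as.data.frame(x))
  x <- x[order(match(x$whale_id, unique(x$whale_id)), x$start_s), ]
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Ordered list of per-whale row-index blocks, preserving first appearance.
split_by_whale <- function(dives) {
  split(seq_len(nrow(dives)),
        factor(dives$whale_id, levels = unique(dives$whale_id)))
}
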