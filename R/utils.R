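# Shared internal helpers: run encoding, half-open intervals, clamping.
# All intervals in this package are half-open [start, end), times POSIXct UTC
# (used as local civil time without DST, matching device clocks).

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Maximal runs of TRUE in a logical vector
#'
#' @param flag logical vector; NA counts as FALSE.
#' @return data.frame with integer columns `start`, `end` (inclusive indices)
#'   and `len`.
#' @keywords internal
true_runs <- function(flag) {
  flag <- as.logical(flag)
  flag[is.na(flag)] <- FALSE
  if (!any(flag)) {
    return(data.frame(start = integer(), end = integer(), len = integer()))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             len = r$lengths[keep])
}

# Fuse index runs (sorted, non-overlapping) whose gap is < max_gap indices.
# Returns runs in the same start/end (inclusive) convention, gap included.
fuse_runs <- function(runs, max_gap) {
  if (nrow(runs) <= 1L) return(runs)
  runs <- runs[order(runs$start), , drop = FALSE]
  out_start <- runs$start[1L]
  out_end <- runs$end[1L]
  starts <- ends <- integer(0)
  for (i in seq_len(nrow(runs))[-1L]) {
    gap <- runs$start[i] - out_end - 1L
    if (gap < max_gap) {
      out_end <- max(out_end, runs$end[i])
    } else {
      starts <- c(starts, out_start); ends <- c(ends, out_end)
      out_start <- runs$start[i]; out_end <- runs$end[i]
    }
  }
  starts <- c(starts, out_start); ends <- c(ends, out_end)
  data.frame(start = starts, end = ends, len = ends - starts + 1L)
}

# Membership of times in any half-open interval [start, end).
in_intervals <- function(times, intervals) {
  out <- rep(FALSE, length(times))
  if (is.null(intervals) || nrow(intervals) == 0L) return(out)
  for (i in seq_len(nrow(intervals))) {
    out <- out | (times >= intervals$start[i] & times < intervals$end[i])
  }
  out
}

# Merge overlapping/touching half-open intervals; warns if any overlapped.
merge_intervals <- function(intervals, warn_overlap = FALSE) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(intervals)
  o <- order(intervals$start)
  s <- intervals$start[o]; e <- intervals$end[o]
  ms <- s[1]; me <- e[1]
  starts <- s[0]; ends <- e[0]
  overlapped <- FALSE
  for (i in seq_along(s)[-1L]) {
    if (s[i] < me) {
      overlapped <- TRUE
      me <- max(me, e[i])
    } else if (s[i] == me) {
      me <- max(me, e[i])
    } else {
      starts <- c(starts, ms); ends <- c(ends, me)
      ms <- s[i]; me <- e[i]
    }
  }
  starts <- c(starts, ms); ends <- c(ends, me)
  if (overlapped && warn_overlap) {
    warning("overlapping intervals were merged", call. = FALSE)
  }
  out <- intervals[seq_along(starts), , drop = FALSE]
  out$start <- starts; out$end <- ends
  out
}

# Midnight-anchored calendar date of a time (UTC treated as civil time).
civil_date <- function(time) as.Date(time, tz = "UTC")

# Noon-anchored "night date": the date whose noon starts the window a time
# falls in, i.e. times in [noon(D), noon(D+1)) map to D.
noon_date <- function(time) as.Date(time - 12 * 3600, tz = "UTC")
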