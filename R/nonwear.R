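# Non-wear detection: two-pass temperature + movement algorithm on the
# 1-minute grid. Pass 1 finds long (>= 90 min) removals against a cohort-free
# threshold T0; pass 2 re-thresholds against a wear-calibrated T1 to find
# short removals in [15, 90) min, guarded by a start-vs-end temperature drop.

#' Non-wear detection configuration
#'
#' Defaults follow the adapted two-pass temperature algorithm: candidate
#' minutes are those where smoothed temperature is below the threshold or
#' falls faster than `t_drop_rate` per minute; long runs (>= `long_min`) with
#' mean ROCAM below `rocam_thresh` are non-wear, runs closer than `merge_gap`
#' are fused; the second pass keeps runs of length `[short_min, short_max)`
#' whose first five minutes are at least `short_temp_drop` warmer than the
#' last five.
#'
#' @param t0_floor pass-1 temperature floor, degrees C.
#' @param t1_cap cap on the pass-2 threshold, degrees C.
#' @param t_drop_rate minute-to-minute smoothed-temperature drop that flags a
#'   candidate minute, degrees C per minute (negative).
#' @param long_min minimum pass-1 run length, minutes.
#' @param short_min,short_max pass-2 run length band `[short_min, short_max)`,
#'   minutes; a run of exactly `short_max` minutes belongs to pass 1.
#' @param merge_gap two non-wear runs closer than this many minutes are fused
#'   including the gap.
#' @param rocam_thresh run-level ROCAM threshold (g per sample interval).
#' @param rocam_stat `"mean"` (default) or `"median"`: how the run-level
#'   ROCAM is summarized before comparison with `rocam_thresh`.
#' @param short_temp_drop required first-5-min minus last-5-min smoothed
#'   temperature drop for pass-2 runs, degrees C.
#' @param min_worn_days_for_t1 if fewer full days than this are worn after
#'   pass 1, the pass-2 threshold is fixed at `t1_cap`.
#' @return list of class `nonwear_config`.
#' @export
nonwear_config <- function(t0_floor = 26, t1_cap = 24, t_drop_rate = -0.5,
                           long_min = 90, short_min = 15, short_max = 90,
                           merge_gap = 15, rocam_thresh = 0.025,
                           rocam_stat = c("mean", "median"),
                           short_temp_drop = 2, min_worn_days_for_t1 = 3) {
  rocam_stat <- match.arg(rocam_stat)
  stopifnot(long_min > 0, short_min > 0, short_max > 0, merge_gap > 0)
  structure(list(
    t0_floor = t0_floor, t1_cap = t1_cap, t_drop_rate = t_drop_rate,
    long_min = long_min, short_min = short_min, short_max = short_max,
    merge_gap = merge_gap, rocam_thresh = rocam_thresh,
    rocam_stat = rocam_stat, short_temp_drop = short_temp_drop,
    min_worn_days_for_t1 = min_worn_days_for_t1
  ), class = "nonwear_config")
}

#' Pass-1 temperature threshold T0
#'
#' `max(t0_floor, 5th percentile of the smoothed temperature series)`.
#' The percentile is computed on the 1-minute `t_smooth` values (the series
#' the rule consumes) with the linear-interpolation definition
#' (`quantile(type = 7)`).
#'
#' @param t_smooth minute-level smoothed temperature, degrees C.
#' @param t0_floor floor, degrees C.
#' @return T0 in degrees C.
#' @export
compute_t0 <- function(t_smooth, t0_floor = 26) {
  t_smooth <- t_smooth[is.finite(t_smooth)]
  if (!length(t_smooth)) stop("no valid temperature readings", call. = FALSE)
  max(t0_floor, unname(quantile(t_smooth, 0.05, type = 7)))
}

# Candidate minutes: temperature below threshold OR minute-to-minute drop
# steeper than t_drop_rate. NA temperature is never a candidate.
nonwear_candidates <- function(t_smooth, threshold, t_drop_rate) {
  dts <- c(NA_real_, diff(t_smooth))
  cand <- (t_smooth < threshold) | (dts < t_drop_rate)
  cand[is.na(cand)] <- FALSE
  cand
}

run_rocam_stat <- function(rocam_min, runs, stat) {
  vapply(seq_len(nrow(runs)), function(i) {
    v <- rocam_min[runs$start[i]:runs$end[i]]
    v <- v[is.finite(v)]
    if (!length(v)) return(Inf)
    if (stat == "mean") mean(v) else median(v)
  }, numeric(1))
}

runs_to_intervals <- function(runs, times) {
  tibble::tibble(start = times[runs$start],
                 end = times[runs$end] + 60)
}

#' Detect long (pass-1) non-wear runs
#'
#' Maximal candidate runs of at least `long_min` minutes whose run-level
#' ROCAM is below `rocam_thresh` are non-wear; any two resulting runs
#' separated by fewer than `merge_gap` minutes are fused including the gap.
#'
#' @param epochs an `epoch_frame` from [epochize()].
#' @param t0 pass-1 threshold from [compute_t0()].
#' @param config a [nonwear_config()].
#' @return tibble of half-open intervals `start`, `end` (POSIXct).
#' @export
detect_long_nonwear <- function(epochs, t0, config = nonwear_config()) {
  m <- epochs$minute
  cand <- nonwear_candidates(m$t_smooth, t0, config$t_drop_rate)
  runs <- true_runs(cand)
  runs <- runs[runs$len >= config$long_min, , drop = FALSE]
  if (nrow(runs)) {
    stat <- run_rocam_stat(m$rocam, runs, config$rocam_stat)
    runs <- runs[stat < config$rocam_thresh, , drop = FALSE]
  }
  runs <- fuse_runs(runs, config$merge_gap)
  runs_to_intervals(runs, m$time)
}

#' Pass-2 temperature threshold T1
#'
#' One standard deviation below the mean worn temperature, capped at
#' `t1_cap`; if the 5th percentile of *all* temperature readings exceeds that
#' value it is used instead; and if fewer than `min_worn_days_for_t1` full
#' days are worn after pass 1, T1 is fixed at `t1_cap`.
#'
#' @param t_smooth minute-level smoothed temperature.
#' @param pass1_mask logical, TRUE for minutes inside pass-1 non-wear.
#' @param config a [nonwear_config()].
#' @return T1 in degrees C.
#' @export
compute_t1 <- function(t_smooth, pass1_mask, config = nonwear_config()) {
  worn <- t_smooth[!pass1_mask & is.finite(t_smooth)]
  if (!length(worn)) stop("no worn minutes after pass 1", call. = FALSE)
  if (length(worn) < config$min_worn_days_for_t1 * 1440) {
    return(config$t1_cap)
  }
  t1 <- min(mean(worn) - sd(worn), config$t1_cap)
  p5_all <- unname(quantile(t_smooth[is.finite(t_smooth)], 0.05, type = 7))
  if (p5_all > t1) t1 <- p5_all
  t1
}

#' Detect short (pass-2) non-wear runs
#'
#' Same thresholding as pass 1 but against `t1`, restricted to minutes
#' outside pass-1 intervals; maximal runs of length `[short_min, short_max)`
#' minutes with run-level ROCAM below threshold are kept only when the mean
#' smoothed temperature over the first five minutes exceeds that over the
#' last five by at least `short_temp_drop` degrees (short removals show a
#' sudden temperature drop).
#'
#' @inheritParams detect_long_nonwear
#' @param t1 pass-2 threshold from [compute_t1()].
#' @param pass1_intervals tibble of pass-1 intervals.
#' @return tibble of half-open intervals `start`, `end`.
#' @export
detect_short_nonwear <- function(epochs, t1, pass1_intervals,
                                 config = nonwear_config()) {
  m <- epochs$minute
  in_p1 <- in_intervals(m$time, pass1_intervals)
  cand <- nonwear_candidates(m$t_smooth, t1, config$t_drop_rate) & !in_p1
  runs <- true_runs(cand)
  runs <- runs[runs$len >= config$short_min & runs$len < config$short_max, ,
               drop = FALSE]
  if (nrow(runs)) {
    stat <- run_rocam_stat(m$rocam, runs, config$rocam_stat)
    runs <- runs[stat < config$rocam_thresh, , drop = FALSE]
  }
  if (nrow(runs)) {
    drop_ok <- vapply(seq_len(nrow(runs)), function(i) {
      idx <- runs$start[i]:runs$end[i]
      first5 <- mean(m$t_smooth[head(idx, 5)], na.rm = TRUE)
      last5 <- mean(m$t_smooth[tail(idx, 5)], na.rm = TRUE)
      isTRUE(first5 - last5 >= config$short_temp_drop)
    }, logical(1))
    runs <- runs[drop_ok, , drop = FALSE]
  }
  runs_to_intervals(runs, m$time)
}

#' Assemble the minute-level wear mask
#'
#' Runs pass 1 (long runs against T0, gap fusion) then pass 2 (short runs
#' against T1 with the temperature-drop guard) and returns a minute grid with
#' a `worn` flag and per-minute provenance (`worn`, `pass1`, `merged_gap`,
#' `pass2`). Also fills the `wear` column of the epoch frame's minute grid
#' and the matching 5-s validity, via the returned mask's attributes.
#'
#' @inheritParams detect_long_nonwear
#' @return tibble of class `wear_mask` with columns `time`, `worn`,
#'   `provenance`; attributes `intervals` (tibble `start`, `end`, `pass`),
#'   `t0`, `t1`.
#' @export
wear_mask <- function(epochs, config = nonwear_config()) {
  m <- epochs$minute
  t0 <- compute_t0(m$t_smooth, config$t0_floor)

  # Pre-merge pass-1 runs are needed to label merged-gap minutes.
  cand <- nonwear_candidates(m$t_smooth, t0, config$t_drop_rate)
  runs <- true_runs(cand)
  runs <- runs[runs$len >= config$long_min, , drop = FALSE]
  if (nrow(runs)) {
    stat <- run_rocam_stat(m$rocam, runs, config$rocam_stat)
    runs <- runs[stat < config$rocam_thresh, , drop = FALSE]
  }
  pre <- runs
  fused <- fuse_runs(runs, config$merge_gap)

  prov <- rep("worn", nrow(m))
  for (i in seq_len(nrow(fused))) prov[fused$start[i]:fused$end[i]] <- "merged_gap"
  for (i in seq_len(nrow(pre))) prov[pre$start[i]:pre$end[i]] <- "pass1"
  pass1_intervals <- runs_to_intervals(fused, m$time)

  t1 <- compute_t1(m$t_smooth, prov != "worn", config)
  pass2_intervals <- detect_short_nonwear(epochs, t1, pass1_intervals, config)
  in_p2 <- in_intervals(m$time, pass2_intervals)
  prov[in_p2] <- "pass2"

  worn <- prov == "worn"
  intervals <- rbind(
    if (nrow(pass1_intervals)) cbind(pass1_intervals, pass = "pass1"),
    if (nrow(pass2_intervals)) cbind(pass2_intervals, pass = "pass2")
  )
  out <- tibble::tibble(time = m$time, worn = worn, provenance = prov)
  attr(out, "intervals") <- tibble::as_tibble(
    intervals %||% data.frame(start = m$time[0], end = m$time[0],
                              pass = character()))
  attr(out, "t0") <- t0
  attr(out, "t1") <- t1
  class(out) <- c("wear_mask", class(out))
  out
}

#' Wear fraction per calendar day
#'
#' @param mask a [wear_mask()].
#' @param anchor `"midnight"` (calendar day) or `"noon"` (noon-to-noon day,
#'   labeled by the date whose noon starts it).
#' @return tibble `date`, `wear_frac`, `n_minutes`.
#' @export
wear_fraction <- function(mask, anchor = c("midnight", "noon")) {
  anchor <- match.arg(anchor)
  date <- if (anchor == "midnight") civil_date(mask$time) else
    noon_date(mask$time)
  agg <- aggregate(mask$worn, by = list(date = date),
                   FUN = function(w) c(mean(w), length(w)))
  tibble::tibble(date = agg$date,
                 wear_frac = agg$x[, 1],
                 n_minutes = as.integer(agg$x[, 2]))
}
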