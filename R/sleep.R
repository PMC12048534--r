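# Sleep: sustained inactivity from the z-angle, the nightly sleep-period-time
# (SPT) window, WASO/efficiency, low-variation periods, and the day-pair
# sleep regularity index (SRI). Sleep days are anchored noon-to-noon.

#' Sustained-inactivity detection on the 5-s z-angle grid
#'
#' A 5-s epoch is inactive iff it lies in a maximal run where every
#' successive absolute z-angle change is below `angle_thresh` degrees and the
#' run spans at least `min_minutes` minutes. Epochs falling in non-worn
#' minutes are invalid (`NA`), not inactive, and break runs.
#'
#' @param angle tibble `time`, `z_angle` on the 5-s grid (from [epochize()]).
#' @param mask optional [wear_mask()]; `NULL` treats everything as worn.
#' @param angle_thresh degrees; successive changes below this count as still.
#' @param min_minutes minimum run span in minutes.
#' @return logical vector along the 5-s grid: `TRUE` inactive, `FALSE`
#'   active, `NA` invalid (non-worn).
#' @export
sustained_inactivity <- function(angle, mask = NULL, angle_thresh = 5,
                                 min_minutes = 5) {
  z <- angle$z_angle
  n <- length(z)
  if (n < 2L) return(rep(NA, n))
  worn <- if (is.null(mask)) rep(TRUE, n) else {
    # map each 5-s epoch onto its minute
    idx <- findInterval(as.numeric(angle$time), as.numeric(mask$time))
    w <- rep(FALSE, n)
    ok <- idx >= 1 & idx <= nrow(mask)
    w[ok] <- mask$worn[idx[ok]]
    w
  }
  small <- abs(diff(z)) < angle_thresh
  # a diff is usable only when both flanking epochs are worn
  small <- small & worn[-n] & worn[-1L]
  small[is.na(small)] <- FALSE
  inactive <- rep(FALSE, n)
  runs <- true_runs(small)
  if (nrow(runs)) {
    # a run of k consecutive small diffs covers k+1 epochs of 5 s
    span_ok <- (runs$len + 1L) * 5 >= min_minutes * 60
    for (i in which(span_ok)) {
      inactive[runs$start[i]:(runs$end[i] + 1L)] <- TRUE
    }
  }
  inactive[!worn] <- NA
  inactive
}

#' Detect the nightly sleep-period-time window
#'
#' Heuristic over one noon-to-noon night window: inactivity runs of at
#' least `block_min` minutes are candidate blocks; blocks separated by less
#' than `fuse_gap` minutes are fused; the SPT is the longest fused block,
#' ties broken toward the block containing 03:00 (then the earlier block).
#' Finally, inactivity fragments of any length lying within 15 minutes of
#' the window edges are absorbed (brief posture changes at sleep onset or
#' offset otherwise split off sub-block fragments and bias the window).
#'
#' @param inactive logical 5-s inactivity series (from
#'   [sustained_inactivity()]).
#' @param times POSIXct 5-s epoch starts matching `inactive`.
#' @param night_start POSIXct noon that opens the night window
#'   `[night_start, night_start + 24 h)`.
#' @param block_min minimum inactivity block, minutes.
#' @param fuse_gap fuse blocks separated by less than this many minutes.
#' @return list `spt_start`, `spt_end` (POSIXct) or `NULL` when no candidate
#'   block exists ("no SPT" night).
#' @export
detect_spt <- function(inactive, times, night_start, block_min = 30,
                       fuse_gap = 60) {
  sel <- times >= night_start & times < night_start + 86400
  z <- inactive[sel]; tt <- times[sel]
  if (!length(z) || !any(z %in% TRUE)) return(NULL)
  all_runs <- true_runs(z)
  runs <- all_runs[all_runs$len * 5 >= block_min * 60, , drop = FALSE]
  if (!nrow(runs)) return(NULL)
  fused <- fuse_runs(runs, as.integer(fuse_gap * 12))  # gap in 5-s epochs
  lens <- fused$len
  best <- which(lens == max(lens))
  if (length(best) > 1L) {
    anchor <- night_start + 15 * 3600  # 03:00 of the following morning
    contains <- vapply(best, function(i) {
      tt[fused$start[i]] <= anchor && anchor < tt[fused$end[i]] + 5
    }, logical(1))
    best <- if (any(contains)) best[which(contains)[1]] else best[1]
  }
  i <- best[1]
  s <- fused$start[i]; e <- fused$end[i]
  # absorb inactivity fragments broken off the window edges by brief
  # posture changes: runs of any length within edge_gap of the span
  edge_gap <- 15L * 12L
  repeat {
    before <- all_runs[all_runs$end < s & s - all_runs$end - 1L < edge_gap, ]
    after <- all_runs[all_runs$start > e & all_runs$start - e - 1L < edge_gap, ]
    if (!nrow(before) && !nrow(after)) break
    if (nrow(before)) s <- min(before$start)
    if (nrow(after)) e <- max(after$end)
  }
  list(spt_start = tt[s], spt_end = tt[e] + 5)
}

#' Sleep metrics within one SPT window
#'
#' Sleep duration is the sustained-inactivity time inside the window, WASO
#' (wake after sleep onset) the remainder, efficiency their ratio.
#'
#' @inheritParams detect_spt
#' @param spt list `spt_start`, `spt_end` from [detect_spt()], or `NULL`.
#' @return list `sleep_min`, `waso_min`, `efficiency` (all `NA` when `spt`
#'   is `NULL`).
#' @export
sleep_metrics <- function(inactive, times, spt) {
  if (is.null(spt)) {
    return(list(sleep_min = NA_real_, waso_min = NA_real_,
                efficiency = NA_real_))
  }
  sel <- times >= spt$spt_start & times < spt$spt_end
  spt_min <- as.numeric(difftime(spt$spt_end, spt$spt_start, units = "mins"))
  sleep_min <- sum(inactive[sel] %in% TRUE) * 5 / 60
  list(sleep_min = sleep_min,
       waso_min = spt_min - sleep_min,
       efficiency = sleep_min / spt_min)
}

#' Low-variation periods from the raw axes
#'
#' Per-minute statistic: the mean over the three axes of the mean absolute
#' successive difference of the axis signal within the minute (computed at
#' epoching time and carried on the minute grid as `lowvar_stat`). Minutes
#' where the statistic is strictly below `threshold`, sustained for at least
#' `min_minutes`, are low-variation. The default threshold was calibrated on
#' synthetic sleep fixtures, not taken from published work.
#'
#' @param epochs an `epoch_frame`.
#' @param threshold g per sample interval; strict inequality.
#' @param min_minutes minimum sustained run, minutes.
#' @return list with `intervals` (tibble `start`, `end`), `minutes` (logical
#'   per-minute flag) and `daily` (tibble `date`, `lowvar_min`).
#' @export
low_variation <- function(epochs, threshold = 0.01, min_minutes = 5) {
  m <- epochs$minute
  low <- m$lowvar_stat < threshold
  low[is.na(low)] <- FALSE
  runs <- true_runs(low)
  runs <- runs[runs$len >= min_minutes, , drop = FALSE]
  flag <- rep(FALSE, nrow(m))
  for (i in seq_len(nrow(runs))) flag[runs$start[i]:runs$end[i]] <- TRUE
  date <- civil_date(m$time)
  daily <- aggregate(flag, by = list(date = date), FUN = sum)
  list(
    intervals = runs_to_intervals(runs, m$time),
    minutes = flag,
    daily = tibble::tibble(date = daily$date, lowvar_min = daily$x)
  )
}

#' Share of low-variation time inside an SPT window
#'
#' @param lowvar result of [low_variation()].
#' @param epochs the `epoch_frame` the flag aligns to.
#' @param spt list `spt_start`, `spt_end`.
#' @return fraction in `[0, 1]`, or `NA` if `spt` is `NULL` or empty flag.
#' @export
low_variation_in_spt <- function(lowvar, epochs, spt) {
  if (is.null(spt)) return(NA_real_)
  tot <- sum(lowvar$minutes)
  if (tot == 0) return(NA_real_)
  sel <- epochs$minute$time >= spt$spt_start &
    epochs$minute$time < spt$spt_end
  sum(lowvar$minutes[sel]) / tot
}

#' 30-s sleep states by majority vote from the 5-s inactivity series
#'
#' Each 30-s epoch takes the majority state of its six 5-s epochs
#' (invalid epochs excluded); ties and all-invalid epochs are invalid.
#'
#' @inheritParams detect_spt
#' @return tibble `time` (30-s grid), `state` (`"sleep"`, `"wake"`, or `NA`).
#' @export
sleep_states_30s <- function(inactive, times) {
  n <- length(inactive)
  nep <- n %/% 6L
  if (nep < 1L) {
    return(tibble::tibble(time = times[0], state = character(0)))
  }
  g <- rep(seq_len(nep), each = 6L)
  x <- inactive[seq_len(nep * 6L)]
  sleep_n <- tapply(x %in% TRUE, g, sum)
  wake_n <- tapply(x %in% FALSE, g, sum)
  state <- ifelse(sleep_n > wake_n, "sleep",
                  ifelse(wake_n > sleep_n, "wake", NA_character_))
  tibble::tibble(time = times[seq(1L, nep * 6L, by = 6L)],
                 state = as.character(state))
}

#' Day-pair sleep regularity index
#'
#' Compares 30-s sleep/wake states 24 h apart between two consecutive days:
#' `SRI = 200 * (fraction of agreeing pairs) - 100`, over epoch pairs valid
#' in both days. 100 means perfectly aligned sleep, -100 perfectly
#' anti-aligned. Missing when the jointly-valid fraction does not exceed
#' `min_valid`.
#'
#' @param states_prev,states_cur character vectors of 30-s states
#'   (`"sleep"`/`"wake"`/`NA`) for day k-1 and day k, equal length.
#' @param min_valid required jointly-valid fraction (strict).
#' @return SRI in `[-100, 100]`, or `NA_real_`.
#' @export
sleep_regularity <- function(states_prev, states_cur, min_valid = 0.8) {
  if (length(states_prev) != length(states_cur)) {
    stop("day-pair state series must have equal length", call. = FALSE)
  }
  valid <- !is.na(states_prev) & !is.na(states_cur)
  if (!any(valid)) return(NA_real_)
  if (mean(valid) <= min_valid) return(NA_real_)
  agree <- mean(states_prev[valid] == states_cur[valid])
  200 * agree - 100
}

#' Nightly sleep table for one recording
#'
#' Runs sustained-inactivity, SPT, WASO/efficiency, and day-pair SRI over
#' every noon-to-noon night of an epoch frame. Nights are labeled by the date
#' whose noon opens the window.
#'
#' @param epochs an `epoch_frame`.
#' @param mask a [wear_mask()].
#' @param spt_block_min,spt_fuse_gap SPT heuristic parameters, minutes.
#' @param sri_min_valid validity threshold for SRI (strict).
#' @return tibble: `night_date`, `spt_start`, `spt_end`, `sleep_min`,
#'   `waso_min`, `efficiency`, `sri`, `validity` (worn fraction of the
#'   noon-to-noon day on the 30-s grid).
#' @export
detect_sleep <- function(epochs, mask, spt_block_min = 30,
                         spt_fuse_gap = 60, sri_min_valid = 0.8) {
  ang <- epochs$angle
  inact <- sustained_inactivity(ang, mask)
  st30 <- sleep_states_30s(inact, ang$time)
  st30$night <- noon_date(st30$time)

  nights <- sort(unique(noon_date(ang$time)))
  # only nights with a full noon-to-noon span of 30-s states
  full <- vapply(nights, function(d) {
    sum(st30$night == d) == 2880L
  }, logical(1))

  rows <- lapply(seq_along(nights), function(i) {
    d <- nights[i]
    ns <- as.POSIXct(paste(d, "12:00:00"), tz = "UTC")
    spt <- detect_spt(inact, ang$time, ns, spt_block_min, spt_fuse_gap)
    met <- sleep_metrics(inact, ang$time, spt)
    states <- st30$state[st30$night == d]
    validity <- if (length(states)) mean(!is.na(states)) else NA_real_
    sri <- NA_real_
    if (i > 1L && full[i] && full[i - 1L] &&
        nights[i - 1L] == d - 1L) {
      prev <- st30$state[st30$night == nights[i - 1L]]
      sri <- sleep_regularity(prev, states, sri_min_valid)
    }
    tibble::tibble(
      night_date = d,
      spt_start = if (is.null(spt)) as.POSIXct(NA) else spt$spt_start,
      spt_end = if (is.null(spt)) as.POSIXct(NA) else spt$spt_end,
      sleep_min = met$sleep_min, waso_min = met$waso_min,
      efficiency = met$efficiency, sri = sri, validity = validity
    )
  })
  do.call(rbind, rows)
}
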