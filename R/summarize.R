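# Cycle-level summarization of daily series: max-gap-3 linear imputation,
# the TKEO and RMSSD day-to-day variability statistics, quartile-mean
# summaries with >=10 / >=20 inclusion rules, and adherence reporting.

#' Linear interpolation of interior gaps up to three days
#'
#' Fills interior runs of at most `max_gap` consecutive missing values by
#' linear interpolation between the bracketing observed values; longer runs
#' and leading/trailing gaps are left missing (no extrapolation). Observed
#' values are never altered.
#'
#' @param x numeric series indexed by consecutive days.
#' @param max_gap longest missing run that is filled.
#' @return `x` with eligible gaps filled.
#' @export
impute_series <- function(x, max_gap = 3) {
  n <- length(x)
  obs <- which(!is.na(x))
  if (length(obs) < 2L) return(x)
  runs <- true_runs(is.na(x))
  if (!nrow(runs)) return(x)
  interior <- runs$start > obs[1] & runs$end < obs[length(obs)]
  fill <- runs[interior & runs$len <= max_gap, , drop = FALSE]
  if (!nrow(fill)) return(x)
  filled <- approx(obs, x[obs], xout = seq_len(n))$y
  for (i in seq_len(nrow(fill))) {
    idx <- fill$start[i]:fill$end[i]
    x[idx] <- filled[idx]
  }
  x
}

#' Teager-Kaiser energy operator of a daily series
#'
#' `TKEO = (1/N) * sum_{i=2}^{N-1} (x_i^2 - x_{i-1} * x_{i+1})`. Note the
#' normalization by the series length N, not by the N-2 summand count; a
#' conventional alternative is available via `conventional = TRUE`.
#'
#' @param x numeric series (missing values removed by the caller).
#' @param conventional divide by N-2 instead of N.
#' @return scalar; `NA` for series shorter than 3.
#' @export
tkeo <- function(x, conventional = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L || anyNA(x)) {
    if (anyNA(x)) x <- x[!is.na(x)]
    n <- length(x)
    if (n < 3L) return(NA_real_)
  }
  s <- sum(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
  s / (if (conventional) n - 2 else n)
}

#' Root mean squared successive differences of a daily series
#'
#' `RMSSD = sqrt((1/N) * sum_{i=1}^{N-1} (x_{i+1} - x_i)^2)`. Note the
#' normalization by N, not N-1; `conventional = TRUE` divides by N-1.
#'
#' @inheritParams tkeo
#' @return non-negative scalar; `NA` for series shorter than 2.
#' @export
rmssd <- function(x, conventional = FALSE) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  s <- sum(diff(x)^2)
  sqrt(s / (if (conventional) n - 1 else n))
}

#' Mean of the upper / lower quartile values
#'
#' Mean of the `ceiling(n/4)` largest (resp. smallest) values; summarizes
#' bounded ordinal daily scales better than the plain quantile.
#'
#' @param x numeric values (missing removed).
#' @param which `"upper"` or `"lower"`.
#' @return scalar mean.
#' @export
quartile_mean <- function(x, which = c("upper", "lower")) {
  which <- match.arg(which)
  x <- x[!is.na(x)]
  n <- length(x)
  if (!n) return(NA_real_)
  k <- ceiling(n / 4)
  s <- sort(x, decreasing = (which == "upper"))
  mean(s[seq_len(k)])
}

#' Summarize daily variables per smartwatch cycle (or participant)
#'
#' For each grouping unit and variable: the mean requires at least
#' `min_n_mean` non-missing daily values; all other statistics (sd, skewness,
#' IQR, quartiles, quartile means, TKEO, RMSSD) require at least
#' `min_n_other`. TKEO/RMSSD are computed on the max-gap-3 imputed series
#' with residual missing values removed. Skewness is the adjusted
#' Fisher-Pearson coefficient.
#'
#' @param daily data frame with columns `participant`, `cycle` (ignored at
#'   participant level), `day` (consecutive integer day index within the
#'   unit) and the variables to summarize.
#' @param vars character vector of variable columns.
#' @param level `"cycle"` or `"participant"`.
#' @param min_n_mean,min_n_other inclusion thresholds.
#' @return long tibble: `participant`, `cycle` (NA at participant level),
#'   `variable`, `statistic`, `value`, `n`.
#' @export
summarize_cycle <- function(daily, vars, level = c("cycle", "participant"),
                            min_n_mean = 10, min_n_other = 20) {
  level <- match.arg(level)
  daily <- as.data.frame(daily)
  key <- if (level == "cycle") c("participant", "cycle") else "participant"
  units <- unique(daily[key])
  out <- list()
  for (u in seq_len(nrow(units))) {
    sel <- rep(TRUE, nrow(daily))
    for (k in key) sel <- sel & daily[[k]] == units[[k]][u]
    sub <- daily[sel, , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    # place values on the consecutive-day grid of the unit
    grid <- seq(min(sub$day), max(sub$day))
    for (v in vars) {
      x <- rep(NA_real_, length(grid))
      x[match(sub$day, grid)] <- sub[[v]]
      nv <- sum(!is.na(x))
      stat <- c(
        mean = if (nv >= min_n_mean) mean(x, na.rm = TRUE) else NA_real_
      )
      if (nv >= min_n_other) {
        xi <- impute_series(x)
        xi <- xi[!is.na(xi)]
        xx <- x[!is.na(x)]
        stat <- c(stat,
          sd = sd(xx),
          skewness = e1071::skewness(xx, type = 2),
          iqr = unname(diff(quantile(xx, c(0.25, 0.75), type = 7))),
          q25 = unname(quantile(xx, 0.25, type = 7)),
          q75 = unname(quantile(xx, 0.75, type = 7)),
          mean_upper_quartile = quartile_mean(xx, "upper"),
          mean_lower_quartile = quartile_mean(xx, "lower"),
          tkeo = tkeo(xi),
          rmssd = rmssd(xi))
      } else {
        stat <- c(stat,
          sd = NA_real_, skewness = NA_real_, iqr = NA_real_,
          q25 = NA_real_, q75 = NA_real_,
          mean_upper_quartile = NA_real_, mean_lower_quartile = NA_real_,
          tkeo = NA_real_, rmssd = NA_real_)
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        participant = units$participant[u],
        cycle = if (level == "cycle") units$cycle[u] else NA_integer_,
        variable = v,
        statistic = names(stat),
        value = unname(stat),
        n = nv
      )
    }
  }
  do.call(rbind, out)
}

#' Adherence over the first 28 days of each smartwatch cycle
#'
#' PROM adherence is the fraction of days 1-28 with a submitted diary entry;
#' watch adherence the fraction of days with wear above `wear_thresh` of the
#' midnight-anchored day. Weekly breakdowns cover days 1-7, 8-14, 15-21,
#' 22-28. A cycle is included only if more than one PROM was submitted in
#' days 1-28 or any smartwatch data was returned; cycles shorter than 28
#' days use the available days as denominator and are flagged.
#'
#' @param diary de-duplicated diary tibble (`participant`, `assoc_date`).
#' @param daily_wear tibble `participant`, `date`, `wear_frac` (midnight
#'   anchored); may be `NULL` for no watch data at all.
#' @param manifest tibble `participant`, `cycle`, `start_date`, `end_date`.
#' @param window_days adherence window length (28).
#' @param wear_thresh wear fraction defining a watch-adherent day (strict >).
#' @return tibble per participant-cycle: adherence fractions, weekly
#'   breakdowns, `included` flag and `short_cycle` flag.
#' @export
adherence <- function(diary, daily_wear, manifest, window_days = 28,
                      wear_thresh = 0.75) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$participant[i]; cy <- manifest$cycle[i]
    d1 <- as.Date(manifest$start_date[i])
    dend <- as.Date(manifest$end_date[i])
    avail <- min(window_days, as.integer(dend - d1) + 1L)
    days <- d1 + seq_len(avail) - 1L

    prom_days <- if (!is.null(diary)) {
      sum(diary$participant == p & diary$assoc_date %in% days)
    } else 0L
    has_watch <- FALSE
    watch_days <- 0L
    weekly_watch <- rep(NA_real_, 4)
    if (!is.null(daily_wear)) {
      dw <- daily_wear[daily_wear$participant == p &
                         daily_wear$date %in% days, , drop = FALSE]
      has_watch <- nrow(dw) > 0
      watch_days <- sum(dw$wear_frac > wear_thresh, na.rm = TRUE)
    }
    week_of <- function(d) pmin(((as.integer(d - d1)) %/% 7L) + 1L, 4L)
    weekly <- function(adherent_dates) {
      vapply(1:4, function(w) {
        wd <- days[week_of(days) == w]
        if (!length(wd)) return(NA_real_)
        sum(adherent_dates %in% wd) / length(wd)
      }, numeric(1))
    }
    prom_dates <- if (!is.null(diary)) {
      diary$assoc_date[diary$participant == p & diary$assoc_date %in% days]
    } else as.Date(character())
    watch_dates <- if (!is.null(daily_wear)) {
      dw <- daily_wear[daily_wear$participant == p &
                         daily_wear$date %in% days, , drop = FALSE]
      dw$date[dw$wear_frac > wear_thresh]
    } else as.Date(character())
    wp <- weekly(prom_dates); ww <- weekly(watch_dates)

    tibble::tibble(
      participant = p, cycle = cy,
      prom_adherence = prom_days / avail,
      watch_adherence = watch_days / avail,
      prom_week1 = wp[1], prom_week2 = wp[2], prom_week3 = wp[3],
      prom_week4 = wp[4],
      watch_week1 = ww[1], watch_week2 = ww[2], watch_week3 = ww[3],
      watch_week4 = ww[4],
      included = prom_days > 1L || has_watch,
      short_cycle = avail < window_days
    )
  })
  out <- do.call(rbind, rows)
  out[out$included, , drop = FALSE]
}
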