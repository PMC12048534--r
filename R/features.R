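# Daily physical-activity and diurnal-rhythm features on midnight-anchored
# days, with the study's 75%/80% validity rules applied at assembly time.

#' Intensity cut-points
#'
#' Acceleration cut-points (in milli-g of minute-mean ENMO) separating
#' inactivity, light, moderate and vigorous activity. Defaults are the usual
#' wrist cut-points (40/100/400 mg); configurable because wrist placement may
#' vary between participants.
#'
#' @param light_lo,mod_lo,vig_lo lower bounds in milli-g; must be increasing.
#' @return list of class `cut_points`.
#' @export
cut_points <- function(light_lo = 40, mod_lo = 100, vig_lo = 400) {
  if (!(light_lo < mod_lo && mod_lo < vig_lo)) {
    stop("cut-points must satisfy light_lo < mod_lo < vig_lo", call. = FALSE)
  }
  structure(list(light_lo = light_lo, mod_lo = mod_lo, vig_lo = vig_lo),
            class = "cut_points")
}

#' M10, L5 and relative amplitude of one day
#'
#' Rolling 10-h (resp. 5-h) window means of minute activity, maximized
#' (resp. minimized) over all window start minutes within the midnight-
#' anchored day; `ra = (m10 - l5) / (m10 + l5)`. Non-worn minutes are
#' excluded from window means; windows missing more than `max_missing_frac`
#' of their minutes are skipped. Ties break toward the earliest start.
#'
#' @param activity numeric minute activity for one day (length 1440).
#' @param worn logical minute wear flags (length 1440); `NULL` = all worn.
#' @param max_missing_frac maximum tolerated missing fraction per window.
#' @return list `m10`, `m10_onset` (hours), `l5`, `l5_onset`, `ra`.
#' @export
m10_l5_ra <- function(activity, worn = NULL, max_missing_frac = 0.25) {
  n <- length(activity)
  if (is.null(worn)) worn <- rep(TRUE, n)
  x <- ifelse(worn, activity, NA_real_)
  roll <- function(width) {
    ok <- !is.na(x)
    cs <- cumsum(c(0, ifelse(ok, x, 0)))
    cn <- cumsum(c(0, as.numeric(ok)))
    starts <- seq_len(n - width + 1L)
    navail <- cn[starts + width] - cn[starts]
    means <- (cs[starts + width] - cs[starts]) / navail
    means[navail < (1 - max_missing_frac) * width] <- NA_real_
    means
  }
  res <- list(m10 = NA_real_, m10_onset = NA_real_, l5 = NA_real_,
              l5_onset = NA_real_, ra = NA_real_)
  if (n < 600L) return(res)
  w10 <- roll(600L)
  if (any(!is.na(w10))) {
    i <- which(w10 == max(w10, na.rm = TRUE))[1]
    res$m10 <- w10[i]; res$m10_onset <- (i - 1) / 60
  }
  w5 <- roll(300L)
  if (any(!is.na(w5))) {
    i <- which(w5 == min(w5, na.rm = TRUE))[1]
    res$l5 <- w5[i]; res$l5_onset <- (i - 1) / 60
  }
  if (!is.na(res$m10) && !is.na(res$l5) && (res$m10 + res$l5) > 0) {
    res$ra <- (res$m10 - res$l5) / (res$m10 + res$l5)
  }
  res
}

#' Intensity-classified minutes of one day
#'
#' Classifies each worn minute by its mean ENMO against the cut-points
#' (lower-inclusive: a minute exactly at `mod_lo` is moderate). Non-worn
#' minutes are uncounted. MVPA = moderate + vigorous. No bout criteria.
#'
#' @param enmo_min minute-mean ENMO in g.
#' @param worn logical wear flags; `NULL` = all worn.
#' @param cuts a [cut_points()] (milli-g).
#' @return list `inactive_min`, `light_min`, `moderate_min`, `vigorous_min`,
#'   `mvpa_min`.
#' @export
intensity_minutes <- function(enmo_min, worn = NULL, cuts = cut_points()) {
  if (is.null(worn)) worn <- rep(TRUE, length(enmo_min))
  mg <- enmo_min[worn & !is.na(enmo_min)] * 1000
  list(
    inactive_min = sum(mg < cuts$light_lo),
    light_min = sum(mg >= cuts$light_lo & mg < cuts$mod_lo),
    moderate_min = sum(mg >= cuts$mod_lo & mg < cuts$vig_lo),
    vigorous_min = sum(mg >= cuts$vig_lo),
    mvpa_min = sum(mg >= cuts$mod_lo)
  )
}

#' Cosinor fit of the diurnal temperature rhythm
#'
#' Least-squares fit of `T(t) = mesor + amplitude * cos(2*pi*(t - acrophase)
#' / 24)` to worn-minute smoothed temperature, with `t` the hour of day.
#' Requires at least `min_worn_frac` of the day's minutes worn. Degenerate
#' (near-constant) input returns amplitude 0 with missing acrophase.
#'
#' @param t_smooth minute smoothed temperature for one day (length 1440).
#' @param worn logical wear flags; `NULL` = all worn.
#' @param hours hour-of-day of each minute; default the 1440-minute grid.
#' @param min_worn_frac minimum worn fraction of the day.
#' @return list `mesor`, `amplitude` (>= 0), `acrophase` (hours in [0, 24)).
#' @export
temperature_rhythm <- function(t_smooth, worn = NULL, hours = NULL,
                               min_worn_frac = 0.5) {
  n <- length(t_smooth)
  if (is.null(worn)) worn <- rep(TRUE, n)
  if (is.null(hours)) hours <- (seq_len(n) - 1) / 60
  use <- worn & !is.na(t_smooth)
  out <- list(mesor = NA_real_, amplitude = NA_real_, acrophase = NA_real_)
  if (mean(use) < min_worn_frac || sum(use) < 4L) return(out)
  y <- t_smooth[use]; h <- hours[use]
  if (sd(y) < 1e-10) {
    return(list(mesor = mean(y), amplitude = 0, acrophase = NA_real_))
  }
  cw <- cos(2 * pi * h / 24); sw <- sin(2 * pi * h / 24)
  fit <- lm(y ~ cw + sw)
  a <- coef(fit)[["cw"]]; b <- coef(fit)[["sw"]]
  amp <- sqrt(a^2 + b^2)
  if (amp < 1e-10) {
    return(list(mesor = unname(coef(fit)[1]), amplitude = 0,
                acrophase = NA_real_))
  }
  phi <- (atan2(b, a) * 24 / (2 * pi)) %% 24
  list(mesor = unname(coef(fit)[1]), amplitude = amp, acrophase = phi)
}

#' Assemble the daily feature table
#'
#' One row per midnight-anchored calendar day combining physical-activity
#' features (from the minute grid), sleep metrics (noon-anchored nights,
#' stored on the night's opening date) and validity flags. Masking rules:
#' PA fields require wear of at least 75% of the midnight-anchored day;
#' sleep fields require at least 75% of the noon-anchored day; SRI
#' additionally requires its own pair validity (already enforced upstream).
#'
#' @param epochs an `epoch_frame`.
#' @param mask a [wear_mask()].
#' @param nights nightly table from [detect_sleep()] (or `NULL`).
#' @param cuts a [cut_points()].
#' @param min_wear_frac validity threshold for both anchors.
#' @return tibble with one row per day: identifiers, wear fractions,
#'   validity flags, M10/L5/RA, intensity minutes, mean ENMO/ROCAM,
#'   temperature cosinor, sleep metrics and SRI.
#' @export
daily_features <- function(epochs, mask, nights = NULL, cuts = cut_points(),
                           min_wear_frac = 0.75) {
  m <- epochs$minute
  date <- civil_date(m$time)
  wf_mid <- wear_fraction(mask, "midnight")
  wf_noon <- wear_fraction(mask, "noon")
  lowvar <- low_variation(epochs)

  days <- sort(unique(date))
  rows <- lapply(days, function(d) {
    sel <- date == d
    full <- sum(sel) == 1440L
    wfm <- wf_mid$wear_frac[match(d, wf_mid$date)]
    # only full 24-h windows can reach validity
    valid_pa <- isTRUE(full && wfm >= min_wear_frac)
    wfn <- wf_noon$wear_frac[match(d, wf_noon$date)]
    n_noon <- wf_noon$n_minutes[match(d, wf_noon$date)]
    valid_sleep <- isTRUE(!is.na(wfn) && n_noon == 1440L &&
                            wfn >= min_wear_frac)

    worn <- mask$worn[sel]
    act <- m$enmo[sel]
    if (valid_pa) {
      ml <- m10_l5_ra(act, worn)
      im <- intensity_minutes(act, worn, cuts)
      tr <- temperature_rhythm(m$t_smooth[sel], worn)
      mean_enmo <- mean(act[worn], na.rm = TRUE)
      mean_rocam <- mean(m$rocam[sel][worn], na.rm = TRUE)
      lv_min <- lowvar$daily$lowvar_min[match(d, lowvar$daily$date)]
    } else {
      ml <- list(m10 = NA_real_, m10_onset = NA_real_, l5 = NA_real_,
                 l5_onset = NA_real_, ra = NA_real_)
      im <- list(inactive_min = NA_real_, light_min = NA_real_,
                 moderate_min = NA_real_, vigorous_min = NA_real_,
                 mvpa_min = NA_real_)
      tr <- list(mesor = NA_real_, amplitude = NA_real_,
                 acrophase = NA_real_)
      mean_enmo <- NA_real_; mean_rocam <- NA_real_; lv_min <- NA_real_
    }

    nt <- if (!is.null(nights)) nights[nights$night_date == d, ] else NULL
    has_night <- !is.null(nt) && nrow(nt) == 1L && valid_sleep
    tibble::tibble(
      participant = epochs$participant_id, date = d,
      wear_frac_midnight = wfm, wear_frac_noon = wfn,
      valid_pa = valid_pa, valid_sleep = valid_sleep,
      m10 = ml$m10, m10_onset = ml$m10_onset, l5 = ml$l5,
      l5_onset = ml$l5_onset, ra = ml$ra,
      inactive_min = im$inactive_min, light_min = im$light_min,
      moderate_min = im$moderate_min, vigorous_min = im$vigorous_min,
      mvpa_min = im$mvpa_min,
      mean_enmo = mean_enmo, mean_rocam = mean_rocam,
      lowvar_min = lv_min,
      temp_mesor = tr$mesor, temp_amplitude = tr$amplitude,
      temp_acrophase = tr$acrophase,
      sleep_min = if (has_night) nt$sleep_min else NA_real_,
      waso_min = if (has_night) nt$waso_min else NA_real_,
      efficiency = if (has_night) nt$efficiency else NA_real_,
      sri = if (has_night) nt$sri else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(paste(out$participant, out$date))) {
    stop("duplicate participant-day in daily feature table", call. = FALSE)
  }
  out
}
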