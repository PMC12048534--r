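# Synthetic cohort generator: raw actigraphy streams and coupled symptom
# diaries with known ground truth (wear intervals, sleep windows, latent
# symptom trajectories, activity-fatigue coupling), so every downstream
# stage is testable without patient data.

#' Synthetic cohort configuration
#'
#' Defaults emulate the study design the package targets: smartwatch cycles
#' of four weeks (up to three per participant), daily pain/BFI diaries with
#' roughly 20% missingness (matching ~80% diary adherence), a within-person
#' fatigue-activity coupling of -0.35 (a "strong" negative association,
#' |R| > 0.3), 28-day symptom cyclicity, and wrist-temperature behavior that
#' separates worn from non-worn states.
#'
#' @param n_participants number of participants (> 0).
#' @param days_per_cycle days per smartwatch cycle.
#' @param n_cycles smartwatch cycles per participant (1-3), contiguous.
#' @param sample_rate raw sampling rate in Hz (1 Hz default keeps synthetic
#'   recordings desk-sized; 10 Hz supported).
#' @param phenotype per-participant symptom phenotype, recycled: one of
#'   `"cyclical"`, `"constant-severe"`, `"flare"`, `"post-surgical"`.
#' @param symptom_period period of the cyclical symptom component, days.
#' @param coupling_fatigue_activity target within-person correlation between
#'   daily activity level and latent fatigue, in `[-1, 1]`.
#' @param prom_missing_rate daily diary missingness probability (MCAR).
#' @param nonwear_events optional data frame `start_min`, `duration_min`
#'   (minutes from recording start) of forced non-wear events; `NULL` samples
#'   events randomly (short daytime removals plus occasional long ones).
#' @param surgery_day 1-based day index of surgery, or `NULL`; must lie
#'   within the recording span.
#' @param sleep_onset_jitter_min SD of nightly sleep onset/offset jitter.
#' @param ambient_temp ambient temperature the device relaxes to when off
#'   the wrist, degrees C.
#' @param noise_scale multiplies every stochastic disturbance (AR noise,
#'   diary item noise, activity disturbance, jitter); 0 gives a fully
#'   deterministic latent trajectory.
#' @param seed integer seed; all randomness derives from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 30, days_per_cycle = 28,
                          n_cycles = 1, sample_rate = 1,
                          phenotype = "cyclical", symptom_period = 28,
                          coupling_fatigue_activity = -0.35,
                          prom_missing_rate = 0.195,
                          nonwear_events = NULL, surgery_day = NULL,
                          sleep_onset_jitter_min = 30, ambient_temp = 21,
                          noise_scale = 1, seed = 1) {
  if (n_participants <= 0) stop("n_participants must be > 0", call. = FALSE)
  if (!n_cycles %in% 1:3) stop("n_cycles must be 1, 2 or 3", call. = FALSE)
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  if (abs(coupling_fatigue_activity) > 1) {
    stop("coupling_fatigue_activity must lie in [-1, 1]", call. = FALSE)
  }
  if (prom_missing_rate < 0 || prom_missing_rate > 1) {
    stop("prom_missing_rate must lie in [0, 1]", call. = FALSE)
  }
  ok <- c("cyclical", "constant-severe", "flare", "post-surgical")
  if (!all(phenotype %in% ok)) {
    stop("unknown phenotype; must be one of ",
         paste(ok, collapse = ", "), call. = FALSE)
  }
  days_total <- days_per_cycle * n_cycles
  if (!is.null(surgery_day) &&
      (surgery_day < 1 || surgery_day > days_total)) {
    stop(sprintf(
      "surgery_day %d is outside the recording span (1..%d days)",
      surgery_day, days_total), call. = FALSE)
  }
  structure(list(
    n_participants = n_participants, days_per_cycle = days_per_cycle,
    n_cycles = n_cycles, sample_rate = sample_rate,
    phenotype = phenotype, symptom_period = symptom_period,
    coupling_fatigue_activity = coupling_fatigue_activity,
    prom_missing_rate = prom_missing_rate,
    nonwear_events = nonwear_events, surgery_day = surgery_day,
    sleep_onset_jitter_min = sleep_onset_jitter_min,
    ambient_temp = ambient_temp, noise_scale = noise_scale,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

participant_phenotype <- function(config, pid) {
  config$phenotype[((pid - 1L) %% length(config$phenotype)) + 1L]
}

participant_seed <- function(config, pid) {
  as.integer((abs(config$seed) %% 100000L) * 20011 + pid * 7919) %%
    2147483647L
}

synth_start_date <- as.Date("2024-03-04")

# AR(1) series of given length (stationary start), vectorized via filter().
ar1_series <- function(n, rho, innov_sd) {
  if (innov_sd == 0 || n == 0) return(rep(0, n))
  innov <- rnorm(n, 0, innov_sd)
  x <- as.numeric(stats::filter(innov, rho, method = "recursive"))
  x * sqrt(1 - rho^2) / 1  # keep roughly stationary scale
}

#' Simulate the latent daily truth of one participant
#'
#' Latent daily fatigue = baseline + cyclical sinusoid + AR(1) noise +
#' flare impulses (phenotype-dependent); latent pain is an affine function
#' of fatigue plus independent noise; the daily activity level is a
#' participant baseline modulated by a disturbance constructed as
#' `c * fatigue_z + sqrt(1 - c^2) * z`, which realizes the target
#' within-person fatigue-activity coupling `c` directly. A post-surgical
#' phenotype drops activity at `surgery_day` and recovers monotonically
#' toward baseline, with a transient symptom flare.
#'
#' @param config a [cohort_config()].
#' @param pid participant index.
#' @return tibble: `day`, `date`, `cycle`, `fatigue`, `pain` (latent,
#'   unclamped scales), `activity` (true daily M10-scale level, g),
#'   `sleep_onset_min`, `sleep_offset_min` (minutes relative to the day's
#'   23:00 / next day's 07:00).
#' @keywords internal
simulate_daily_truth <- function(config, pid) {
  phen <- participant_phenotype(config, pid)
  ns <- config$noise_scale
  days <- config$days_per_cycle * config$n_cycles
  day <- seq_len(days)

  pars <- switch(phen,
    "cyclical" = list(b = 4, amp = 2),
    "constant-severe" = list(b = 7, amp = 0),
    "flare" = list(b = 3, amp = 0.8),
    "post-surgical" = list(b = 4, amp = 1.2))
  phase <- runif(1, 0, 2 * pi)
  fat <- pars$b + pars$amp * sin(2 * pi * day / config$symptom_period +
                                   phase) +
    ar1_series(days, 0.6, 0.8 * ns)
  if (phen == "constant-severe") {
    fat <- fat + ar1_series(days, 0.3, 0.4 * ns)
  }
  if (phen == "flare") {
    ev <- which(runif(days) < 1 / 14)
    for (e in ev) {
      mag <- (1 + rexp(1, 1 / 2)) * ns
      lag <- day - e
      fat <- fat + ifelse(lag >= 0, mag * exp(-lag / 2), 0)
    }
  }
  surgery_factor <- rep(1, days)
  sday <- config$surgery_day
  if (!is.null(sday) && phen == "post-surgical") {
    post <- day >= sday
    fat[post] <- fat[post] + 3.5 * exp(-(day[post] - sday) / 5)
    surgery_factor[post] <- 1 - 0.6 * exp(-(day[post] - sday) / 8)
  }
  pain <- 1 + 0.8 * fat + rnorm(days, 0, 0.7 * ns)

  fz <- if (isTRUE(sd(fat) > 0)) as.numeric(scale(fat)) else rep(0, days)
  cc <- config$coupling_fatigue_activity
  dist <- cc * fz + sqrt(1 - cc^2) * rnorm(days, 0, ns)
  a0 <- max(0.015, 0.030 + rnorm(1, 0, 0.006 * ns))
  activity <- a0 * pmax(0.2, 1 + 0.25 * dist) * surgery_factor

  onset_j <- rnorm(days, 0, config$sleep_onset_jitter_min * ns)
  offset_j <- rnorm(days, 0, config$sleep_onset_jitter_min * ns)

  tibble::tibble(
    day = day,
    date = synth_start_date + day - 1L,
    cycle = ((day - 1L) %/% config$days_per_cycle) + 1L,
    fatigue = fat, pain = pain, activity = activity,
    sleep_onset_min = onset_j, sleep_offset_min = offset_j
  )
}

# Diary + EHP-30 generation from latent truth (ordinal discretization,
# clamping to scale bounds, MCAR missingness).
simulate_proms <- function(config, pid, truth) {
  ns <- config$noise_scale
  days <- nrow(truth)
  pain_avg <- clamp(round(truth$pain + rnorm(days, 0, 0.5 * ns)), 1, 10)
  pain_worst <- clamp(round(truth$pain + 1 + abs(rnorm(days, 0, 0.7 * ns))),
                      1, 10)
  bfi <- matrix(vapply(1:9, function(q) {
    clamp(round(truth$fatigue + rnorm(days, 0, 0.6 * ns)), 0, 10)
  }, numeric(days)), nrow = days)
  submitted <- as.POSIXct(paste(truth$date, "20:00:00"), tz = "UTC") +
    round(rnorm(days, 0, 40 * 60 * ns))
  present <- runif(days) >= config$prom_missing_rate
  diary <- tibble::tibble(
    participant = pid, assoc_date = truth$date, submitted_at = submitted,
    pain_avg = as.numeric(pain_avg), pain_worst = as.numeric(pain_worst)
  )
  for (q in 1:9) diary[[paste0("bfi_q", q)]] <- as.numeric(bfi[, q])
  diary <- diary[present, , drop = FALSE]

  ehp <- lapply(sort(unique(truth$cycle)), function(cy) {
    sub <- truth[truth$cycle == cy, ]
    sev <- clamp(quartile_mean(clamp(sub$pain, 0, 10), "upper") * 0.4, 0, 4)
    items <- clamp(round(sev + rnorm(30, 0, 0.5 * ns)), 0, 4)
    row <- tibble::tibble(participant = pid, cycle = cy)
    for (i in 1:30) row[[sprintf("item_%02d", i)]] <- as.numeric(items[i])
    row
  })
  list(diary = diary, ehp30 = do.call(rbind, ehp))
}

# Sample random non-wear events for a recording of `days` days:
# frequent short daytime removals plus occasional long (work/overnight)
# ones. Returns data.frame(start_min, duration_min).
sample_nonwear_events <- function(days) {
  starts <- durs <- numeric(0)
  for (d in seq_len(days)) {
    if (runif(1) < 0.30) {
      starts <- c(starts, (d - 1) * 1440 + runif(1, 9 * 60, 20 * 60))
      durs <- c(durs, runif(1, 20, 240))
    }
    if (runif(1) < 0.06) {
      starts <- c(starts, (d - 1) * 1440 + runif(1, 8 * 60, 12 * 60))
      durs <- c(durs, runif(1, 360, 840))
    }
  }
  data.frame(start_min = starts, duration_min = durs)
}

#' Simulate one participant: raw streams, diaries, EHP-30 and ground truth
#'
#' Builds the raw tri-axial acceleration/temperature/light stream from the
#' participant's latent daily truth: a diurnal rest/active profile with
#' bout-level movement whose amplitude tracks the daily activity level,
#' nightly sleep windows with onset/offset jitter, wrist temperature around
#' 31 degrees C while worn, and injected non-wear (frozen orientation plus
#' exponential temperature decay toward ambient). The recording is seeded
#' deterministically from `(config$seed, pid)`.
#'
#' @param config a [cohort_config()].
#' @param pid participant index.
#' @param raw generate the raw stream? `FALSE` returns only diaries and
#'   ground truth (fast path for statistics-level simulations).
#' @return list `recording` ([raw_recording()] or `NULL`), `diary`,
#'   `ehp30`, `truth` (list: `daily`, `sleep_intervals`,
#'   `nonwear_intervals`, `wear_intervals`), `manifest` (one row per cycle).
#' @export
simulate_participant <- function(config, pid, raw = TRUE) {
  set.seed(participant_seed(config, pid))
  truth_daily <- simulate_daily_truth(config, pid)
  proms <- simulate_proms(config, pid, truth_daily)
  days <- nrow(truth_daily)
  start <- as.POSIXct(paste(synth_start_date, "00:00:00"), tz = "UTC")

  # nightly sleep windows: 23:00 + jitter to 07:00 next day + jitter
  onset <- start + (truth_daily$day - 1) * 86400 + 23 * 3600 +
    round(truth_daily$sleep_onset_min * 60)
  offset <- start + truth_daily$day * 86400 + 7 * 3600 +
    round(truth_daily$sleep_offset_min * 60)
  sleep_intervals <- tibble::tibble(start = onset, end = offset)

  ev <- config$nonwear_events %||% sample_nonwear_events(days)
  nonwear_intervals <- if (nrow(ev)) {
    ev_start <- start + round(ev$start_min * 60)
    ev_end <- start + round((ev$start_min + ev$duration_min) * 60)
    ivs <- tibble::tibble(start = ev_start, end = ev_end)
    ivs$end <- pmin(ivs$end, start + days * 86400)
    ivs <- ivs[ivs$start < ivs$end, ]
    merge_intervals(ivs)
  } else tibble::tibble(start = start[0], end = start[0])

  wrist <- if (pid %% 5 == 0) "dominant" else "non-dominant"
  manifest <- tibble::tibble(
    participant = pid,
    cycle = seq_len(config$n_cycles),
    start_date = synth_start_date +
      (seq_len(config$n_cycles) - 1L) * config$days_per_cycle,
    end_date = synth_start_date +
      seq_len(config$n_cycles) * config$days_per_cycle - 1L,
    surgery_date = if (is.null(config$surgery_day)) as.Date(NA) else
      synth_start_date + config$surgery_day - 1L,
    wrist = wrist
  )

  recording <- NULL
  if (raw) {
    recording <- build_raw_stream(config, pid, truth_daily,
                                  sleep_intervals, wrist)
    recording <- inject_nonwear(recording, nonwear_intervals,
                                ambient = config$ambient_temp)
  }
  span_end <- start + days * 86400
  truth <- list(
    daily = truth_daily,
    sleep_intervals = sleep_intervals,
    nonwear_intervals = nonwear_intervals,
    wear_intervals = invert_intervals(nonwear_intervals, start, span_end)
  )
  list(recording = recording, diary = proms$diary, ehp30 = proms$ehp30,
       truth = truth, manifest = manifest)
}

invert_intervals <- function(intervals, span_start, span_end) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(tibble::tibble(start = span_start, end = span_end))
  }
  iv <- merge_intervals(intervals)
  starts <- c(span_start, iv$end)
  ends <- c(iv$start, span_end)
  keep <- starts < ends
  tibble::tibble(start = starts[keep], end = ends[keep])
}

# Raw stream synthesis (fully worn; non-wear injected afterwards).
build_raw_stream <- function(config, pid, truth_daily, sleep_intervals,
                             wrist) {
  ns <- config$noise_scale
  rate <- config$sample_rate
  days <- nrow(truth_daily)
  nmin <- days * 1440L
  start <- as.POSIXct(paste(synth_start_date, "00:00:00"), tz = "UTC")
  minute_t <- start + 60 * (seq_len(nmin) - 1L)
  dayix <- ((seq_len(nmin) - 1L) %/% 1440L) + 1L
  tod_h <- (((seq_len(nmin) - 1L) %% 1440L)) / 60

  asleep <- in_intervals(minute_t, sleep_intervals)

  # diurnal activity shape and bout process for wake minutes
  shape <- ifelse(tod_h > 6.5 & tod_h < 23,
                  pmax(0.15, sin(pi * (tod_h - 6.5) / 16.5)), 0.15)
  bout <- ifelse(runif(nmin) < 0.6, exp(rnorm(nmin, 0, 0.5 * ns)), 0.12)
  amp <- truth_daily$activity[dayix] / 0.63 * shape * bout
  amp[asleep] <- 0

  # per-minute gravity orientation: random-walk-with-jumps while awake,
  # a few posture changes per night while asleep
  jump <- (runif(nmin) < ifelse(asleep, 3 / 480, 0.75))
  jump[1] <- TRUE
  oid <- cumsum(jump)
  k <- max(oid)
  th <- runif(k, 0, pi); ph <- runif(k, 0, 2 * pi)
  ux <- (sin(th) * cos(ph))[oid]
  uy <- (sin(th) * sin(ph))[oid]
  uz <- (cos(th))[oid]

  # wrist temperature while worn: ~31.5 C with a realistic spread --
  # warmest during sleep (~03:00), coolest mid-afternoon -- plus slow drift,
  # so the adaptive 5th-percentile thresholds land among cool *active*
  # daytime minutes rather than sleep
  temp_min <- 31.5 + rnorm(1, 0, 0.5 * ns) +
    0.8 * cos(2 * pi * (tod_h - 3) / 24) +
    ar1_series(nmin, 0.995, 0.4 * ns)
  light_min <- pmax(0, 150 * shape * (!asleep) + rnorm(nmin, 0, 5 * ns))

  # expand to samples
  spm <- as.integer(round(rate * 60))
  n <- nmin * spm
  rep_min <- function(x) rep(x, each = spm)
  amps <- rep_min(amp)
  mag <- abs(rnorm(n, 0, 1)) * amps * 4.5
  mx <- rnorm(n); my <- rnorm(n); mz <- rnorm(n)
  mn <- sqrt(mx^2 + my^2 + mz^2)
  ax <- rep_min(ux) + mag * mx / mn + rnorm(n, 0, 0.004)
  ay <- rep_min(uy) + mag * my / mn + rnorm(n, 0, 0.004)
  az <- rep_min(uz) + mag * mz / mn + rnorm(n, 0, 0.004)

  raw_recording(
    tibble::tibble(
      timestamp = start + (seq_len(n) - 1L) / rate,
      ax_g = clamp(ax, -8, 8), ay_g = clamp(ay, -8, 8),
      az_g = clamp(az, -8, 8),
      temp_c = clamp(rep_min(temp_min), 0, 60),
      light_lux = clamp(rep_min(light_min), 0, 3000)
    ),
    participant_id = pid, sample_rate = rate, wrist = wrist,
    calibrated = TRUE
  )
}

#' Inject non-wear into a recording
#'
#' Within each interval the acceleration is frozen to the orientation at the
#' interval start plus a small sensor-noise floor, and the temperature
#' relaxes exponentially toward `ambient` (cooling time constant
#' `tau_cool_min`); after the interval the temperature rewarms toward the
#' worn trace with time constant `tau_rewarm_min`. Outside the intervals
#' (and their rewarming tails) the recording is unchanged. Overlapping
#' intervals are merged with a warning.
#'
#' @param recording a [raw_recording()].
#' @param intervals tibble of half-open POSIXct intervals `start`, `end`.
#' @param ambient ambient temperature, degrees C (below 24).
#' @param tau_cool_min,tau_rewarm_min time constants, minutes.
#' @return The modified recording.
#' @export
inject_nonwear <- function(recording, intervals, ambient = 21,
                           tau_cool_min = 5, tau_rewarm_min = 3) {
  stopifnot(inherits(recording, "raw_recording"))
  if (is.null(intervals) || nrow(intervals) == 0L) return(recording)
  span_start <- recording$data$timestamp[1]
  span_end <- span_start + nrow(recording$data) / recording$sample_rate
  if (any(intervals$start < span_start | intervals$end > span_end)) {
    stop("non-wear intervals must lie within the recording", call. = FALSE)
  }
  intervals <- merge_intervals(intervals, warn_overlap = TRUE)
  d <- recording$data
  ts <- as.numeric(d$timestamp)
  worn_temp <- d$temp_c
  for (i in seq_len(nrow(intervals))) {
    s <- as.numeric(intervals$start[i]); e <- as.numeric(intervals$end[i])
    idx <- which(ts >= s & ts < e)
    if (!length(idx)) next
    i0 <- idx[1]
    g <- c(d$ax_g[i0], d$ay_g[i0], d$az_g[i0])
    g <- g / sqrt(sum(g^2))
    nidx <- length(idx)
    d$ax_g[idx] <- g[1] + rnorm(nidx, 0, 0.002)
    d$ay_g[idx] <- g[2] + rnorm(nidx, 0, 0.002)
    d$az_g[idx] <- g[3] + rnorm(nidx, 0, 0.002)
    t_at_start <- worn_temp[i0]
    dt_min <- (ts[idx] - s) / 60
    d$temp_c[idx] <- ambient + (t_at_start - ambient) *
      exp(-dt_min / tau_cool_min)
    d$light_lux[idx] <- pmax(0, 50 + rnorm(nidx, 0, 2))
    # rewarming tail after the interval, up to the next interval
    t_end <- d$temp_c[idx[nidx]]
    tail_end <- if (i < nrow(intervals)) {
      min(as.numeric(intervals$start[i + 1]), e + 3600)
    } else min(as.numeric(span_end), e + 3600)
    ridx <- which(ts >= e & ts < tail_end)
    if (length(ridx)) {
      rdt <- (ts[ridx] - e) / 60
      d$temp_c[ridx] <- worn_temp[ridx] +
        (t_end - worn_temp[ridx]) * exp(-rdt / tau_rewarm_min)
    }
  }
  recording$data <- d
  recording
}

#' Simulate a whole cohort
#'
#' Runs [simulate_participant()] for each participant (each seeded
#' deterministically from `config$seed` and the participant index) and
#' assembles the cohort manifest.
#'
#' @param config a [cohort_config()].
#' @param raw generate raw streams (`FALSE` = truth/diaries only).
#' @return list of class `cohort_bundle`: `participants` (list of
#'   per-participant results), `manifest`, `diary`, `ehp30`, `config`.
#' @export
simulate_cohort <- function(config, raw = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  parts <- lapply(seq_len(config$n_participants), function(pid) {
    simulate_participant(config, pid, raw = raw)
  })
  manifest <- do.call(rbind, lapply(parts, `[[`, "manifest"))
  diary <- do.call(rbind, lapply(parts, `[[`, "diary"))
  ehp30 <- do.call(rbind, lapply(parts, `[[`, "ehp30"))
  structure(list(participants = parts, manifest = manifest,
                 diary = diary, ehp30 = ehp30, config = config),
            class = "cohort_bundle")
}

#' Daily ground-truth table of a cohort
#'
#' One row per participant-day joining the latent truth (daily activity
#' level on the M10 scale, latent fatigue/pain) with the scored diary
#' (global pain, global BFI), ready for the statistics layer.
#'
#' @param bundle a [simulate_cohort()] result.
#' @return tibble: `participant`, `date`, `day`, `cycle`, `enroll_day`,
#'   `m10`, `fatigue_latent`, `pain_latent`, `global_pain`, `global_bfi`.
#' @export
cohort_daily_truth <- function(bundle) {
  rows <- lapply(bundle$participants, function(p) {
    td <- p$truth$daily
    out <- tibble::tibble(
      participant = p$manifest$participant[1],
      date = td$date, day = td$day, cycle = td$cycle,
      enroll_day = td$day,
      m10 = td$activity,
      fatigue_latent = td$fatigue, pain_latent = td$pain
    )
    if (nrow(p$diary)) {
      sc <- score_daily(p$diary)
      m <- match(out$date, sc$assoc_date)
      out$global_pain <- sc$global_pain[m]
      out$global_bfi <- sc$global_bfi[m]
    } else {
      out$global_pain <- NA_real_
      out$global_bfi <- NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' Write a cohort bundle to plain-text files
#'
#' Raw recordings to the raw actigraphy CSV schema, diary and EHP-30 CSVs,
#' the manifest CSV, and ground-truth labels to a JSON sidecar per
#' participant.
#'
#' @param bundle a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(bundle$manifest, file.path(dir, "manifest.csv"))
  data.table::fwrite(bundle$diary, file.path(dir, "diary.csv"))
  data.table::fwrite(bundle$ehp30, file.path(dir, "ehp30.csv"))
  for (p in bundle$participants) {
    pid <- p$manifest$participant[1]
    if (!is.null(p$recording)) {
      write_raw(p$recording,
                file.path(dir, sprintf("raw_p%03d.csv", pid)))
    }
    truth <- list(
      daily = p$truth$daily,
      sleep_intervals = data.frame(
        start = format(p$truth$sleep_intervals$start, "%Y-%m-%dT%H:%M:%S"),
        end = format(p$truth$sleep_intervals$end, "%Y-%m-%dT%H:%M:%S")),
      nonwear_intervals = data.frame(
        start = format(p$truth$nonwear_intervals$start,
                       "%Y-%m-%dT%H:%M:%S"),
        end = format(p$truth$nonwear_intervals$end, "%Y-%m-%dT%H:%M:%S"))
    )
    jsonlite::write_json(truth,
                         file.path(dir, sprintf("truth_p%03d.json", pid)),
                         dataframe = "columns", pretty = TRUE)
  }
  invisible(dir)
}

#' Standard non-wear fixture events for one recording
#'
#' A deterministic ladder of non-wear durations spanning the short and long
#' detection bands (15 min to 6 h), placed at seeded daytime start times
#' (at most two events per day, morning and afternoon slots, so events never
#' overlap). The total non-wear load (~11% of a week) matches a realistic
#' wear-adherence level, which keeps the adaptive temperature thresholds in
#' their intended regime. Uses the current RNG state; set a seed first.
#'
#' @param days recording length in days (>= 5).
#' @return data frame `start_min`, `duration_min` for
#'   [cohort_config()]'s `nonwear_events`.
#' @export
fixture_nonwear_events <- function(days = 7) {
  stopifnot(days >= 5)
  durs <- c(15, 30, 45, 60, 90, 120, 180, 240, 360)
  day_slot <- sample(rep(seq_len(days), length.out = length(durs)))
  seen <- integer(0)
  start_h <- vapply(day_slot, function(d) {
    slot <- sum(seen == d)
    seen <<- c(seen, d)
    if (slot == 0) runif(1, 9, 11.5) else runif(1, 15.5, 17.5)
  }, numeric(1))
  data.frame(start_min = (day_slot - 1) * 1440 + start_h * 60,
             duration_min = durs)
}
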