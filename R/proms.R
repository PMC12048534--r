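# PROMs: de-duplication of daily symptom diaries, global pain / BFI scoring,
# and EHP-30 subdomain scoring with 0-100 normalization.

#' EHP-30 subdomain item map
#'
#' The published instrument layout: pain (11 items), control and
#' powerlessness (6), emotional wellbeing (6), social support (4),
#' self-image (3). Alternative mappings can be supplied to [score_ehp30()].
#'
#' @return named list mapping subdomain to item indices (1-30).
#' @export
ehp30_domains <- function() {
  list(
    pain_ehp30 = 1:11,
    control_ehp30 = 12:17,
    emotion_ehp30 = 18:23,
    social_ehp30 = 24:27,
    self_ehp30 = 28:30
  )
}

# Classify a submission time against its associated date.
# correct: [17:00 assoc day, 05:00 next day); feasible: anytime on the
# associated day or the following day; otherwise "outside".
classify_window <- function(submitted_at, assoc_date) {
  d0 <- as.POSIXct(paste(assoc_date, "00:00:00"), tz = "UTC")
  corr_lo <- d0 + 17 * 3600
  corr_hi <- d0 + 29 * 3600
  feas_lo <- d0
  feas_hi <- d0 + 48 * 3600
  ifelse(submitted_at >= corr_lo & submitted_at < corr_hi, "correct",
         ifelse(submitted_at >= feas_lo & submitted_at < feas_hi,
                "feasible", "outside"))
}

#' De-duplicate daily diary entries
#'
#' Entries submitted between 17:00 on the associated date and 05:00 the next
#' morning are in the "correct" window; anytime on the associated day or the
#' following day is "feasible". Per participant-date, a correct-window entry
#' is preferred over a feasible one; among equals the earliest submission is
#' kept. Entries outside both windows are dropped (returned in the
#' `dropped` attribute).
#'
#' @param diary data frame with columns `participant`, `assoc_date` (Date),
#'   `submitted_at` (POSIXct) plus item columns.
#' @return tibble with one row per participant-date and a `window_class`
#'   column; dropped rows in `attr(, "dropped")`.
#' @export
deduplicate_diary <- function(diary) {
  diary <- tibble::as_tibble(diary)
  diary$assoc_date <- as.Date(diary$assoc_date)
  diary$window_class <- classify_window(diary$submitted_at,
                                        diary$assoc_date)
  dropped <- diary[diary$window_class == "outside", ]
  keep <- diary[diary$window_class != "outside", ]
  if (nrow(keep)) {
    pref <- ifelse(keep$window_class == "correct", 0L, 1L)
    o <- order(keep$participant, keep$assoc_date, pref, keep$submitted_at)
    keep <- keep[o, ]
    dup <- duplicated(keep[, c("participant", "assoc_date")])
    keep <- keep[!dup, ]
    keep <- keep[order(keep$participant, keep$assoc_date), ]
  }
  attr(keep, "dropped") <- dropped
  keep
}

#' Score one daily diary table into per-day global scores
#'
#' `global_pain` is the mean of the two pain items (average and worst pain
#' today, each 1-10); `global_bfi` the mean of the nine Brief Fatigue
#' Inventory items (each 0-10). Rows with any missing BFI item get a missing
#' `global_bfi`; out-of-range items raise an error naming the item.
#'
#' @param entries data frame with columns `pain_avg`, `pain_worst`,
#'   `bfi_q1` .. `bfi_q9` (plus identifiers, passed through).
#' @return the input tibble with `global_pain` and `global_bfi` appended.
#' @export
score_daily <- function(entries) {
  entries <- tibble::as_tibble(entries)
  bfi_cols <- paste0("bfi_q", 1:9)
  for (col in c("pain_avg", "pain_worst")) {
    v <- entries[[col]]
    if (any(!is.na(v) & (v < 1 | v > 10))) {
      stop("item out of range [1, 10]: ", col, call. = FALSE)
    }
  }
  for (col in bfi_cols) {
    v <- entries[[col]]
    if (any(!is.na(v) & (v < 0 | v > 10))) {
      stop("item out of range [0, 10]: ", col, call. = FALSE)
    }
  }
  entries$global_pain <- (entries$pain_avg + entries$pain_worst) / 2
  bfi <- as.matrix(entries[bfi_cols])
  gb <- rowMeans(bfi)
  gb[rowSums(is.na(bfi)) > 0] <- NA_real_
  entries$global_bfi <- gb
  entries
}

#' Score EHP-30 responses into normalized subdomain scores
#'
#' Each of the 30 items is on a 0 (never) to 4 (always) scale. Each
#' subdomain score is `100 * sum(items) / (4 * n_items)`, i.e. normalized to
#' 0-100 (higher = worse); `ehp30_overall` uses all 30 items. By default any
#' missing item makes the affected score(s) missing; `max_missing` relaxes
#' this per scale (missing items are then dropped from both sums).
#'
#' @param responses numeric vector of 30 items, or a data frame with columns
#'   `item_01` .. `item_30` (plus identifiers, passed through).
#' @param domains subdomain item map, see [ehp30_domains()].
#' @param max_missing maximum missing items tolerated per scale.
#' @return named list of scores for a vector input; a tibble with score
#'   columns appended for data-frame input.
#' @export
score_ehp30 <- function(responses, domains = ehp30_domains(),
                        max_missing = 0) {
  score_one <- function(items) {
    if (any(!is.na(items) & (items < 0 | items > 4))) {
      stop("EHP-30 item out of range [0, 4]", call. = FALSE)
    }
    scales <- c(domains, list(ehp30_overall = 1:30))
    vapply(scales, function(idx) {
      v <- items[idx]
      if (sum(is.na(v)) > max_missing) return(NA_real_)
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      100 * sum(v) / (4 * length(v))
    }, numeric(1))
  }
  if (is.data.frame(responses)) {
    cols <- sprintf("item_%02d", 1:30)
    miss <- setdiff(cols, names(responses))
    if (length(miss)) {
      stop("missing EHP-30 item column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    mat <- as.matrix(responses[cols])
    sc <- t(apply(mat, 1L, score_one))
    out <- tibble::as_tibble(responses)
    for (nm in colnames(sc)) out[[nm]] <- sc[, nm]
    out
  } else {
    if (length(responses) != 30L) {
      stop("EHP-30 requires 30 item responses", call. = FALSE)
    }
    as.list(score_one(responses))
  }
}

#' Read, de-duplicate and score a daily diary CSV
#'
#' Schema: `participant, assoc_date, submitted_at, pain_avg, pain_worst,
#' bfi_q1..bfi_q9`.
#'
#' @param path CSV path.
#' @return scored, de-duplicated tibble (one row per participant-date).
#' @export
read_diary <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  df$assoc_date <- as.Date(df$assoc_date)
  df$submitted_at <- as.POSIXct(df$submitted_at, tz = "UTC")
  score_daily(deduplicate_diary(df))
}
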