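# Shared fixtures and independent brute-force oracles.

t_origin <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")

# Construct an epoch frame directly from minute-level series (and an
# optional constant/vector z-angle on the 5-s grid), bypassing raw signal
# synthesis for precise threshold tests.
make_epoch_frame <- function(n_min, t_smooth = 31, rocam = 0.1,
                             enmo = 0.05, lowvar = 0.05, angle = 0,
                             start = t_origin) {
  n5 <- n_min * 12L
  structure(list(
    minute = tibble::tibble(
      time = start + 60 * (seq_len(n_min) - 1L),
      enmo = rep_len(enmo, n_min),
      rocam = rep_len(rocam, n_min),
      t_smooth = rep_len(t_smooth, n_min),
      light_mean = rep_len(100, n_min),
      lowvar_stat = rep_len(lowvar, n_min),
      wear = rep(NA, n_min)),
    angle = tibble::tibble(
      time = start + 5 * (seq_len(n5) - 1L),
      z_angle = rep_len(angle, n5)),
    participant_id = "T", wrist = "non-dominant",
    sample_rate = 1, start_time = start), class = "epoch_frame")
}

make_mask <- function(epochs, worn) {
  out <- tibble::tibble(time = epochs$minute$time,
                        worn = rep_len(worn, nrow(epochs$minute)),
                        provenance = ifelse(rep_len(worn,
                                                    nrow(epochs$minute)),
                                            "worn", "pass1"))
  class(out) <- c("wear_mask", class(out))
  out
}

# Brute-force rmcorr oracle: explicit ANCOVA via lm with subject factor
# entered first, x last (sequential SS of x = its partial SS).
bf_rmcorr <- function(x, y, subject) {
  d <- data.frame(x = x, y = y, subject = factor(subject))
  d <- d[complete.cases(d), ]
  tab <- table(d$subject)
  d <- d[d$subject %in% names(tab)[tab >= 2], ]
  d$subject <- droplevels(d$subject)
  fit <- lm(y ~ subject + x, data = d)
  a <- anova(fit)
  ss_x <- a["x", "Sum Sq"]; ss_e <- a["Residuals", "Sum Sq"]
  list(r = unname(sign(coef(fit)[["x"]]) * sqrt(ss_x / (ss_x + ss_e))),
       df = a["Residuals", "Df"],
       p = a["x", "Pr(>F)"])
}

# Brute-force M10/L5: exhaustive scan over every window start.
bf_m10_l5 <- function(activity, worn = NULL, max_missing_frac = 0.25) {
  n <- length(activity)
  if (is.null(worn)) worn <- rep(TRUE, n)
  x <- ifelse(worn, activity, NA_real_)
  scan <- function(width, maximize) {
    best <- NA_real_; best_i <- NA_integer_
    for (i in seq_len(n - width + 1L)) {
      w <- x[i:(i + width - 1L)]
      if (mean(is.na(w)) > max_missing_frac) next
      m <- mean(w, na.rm = TRUE)
      if (is.na(best) || (maximize && m > best) ||
          (!maximize && m < best)) {
        best <- m; best_i <- i
      }
    }
    c(best, (best_i - 1) / 60)
  }
  m10 <- scan(600L, TRUE); l5 <- scan(300L, FALSE)
  list(m10 = m10[1], m10_onset = m10[2], l5 = l5[1], l5_onset = l5[2])
}

# Literal-sum oracles for the day-to-day variability statistics.
bf_tkeo <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  s <- 0
  for (i in 2:(n - 1)) s <- s + x[i]^2 - x[i - 1] * x[i + 1]
  s / n
}
bf_rmssd <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  s <- 0
  for (i in 1:(n - 1)) s <- s + (x[i + 1] - x[i])^2
  sqrt(s / n)
}

# Three-variable partial correlation closed form.
bf_partial3 <- function(rxy, rxz, rzy) {
  (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
}

# Simulate directly from the standardized symptom mixed model: response =
# beta2 * m10 + random intercept + AR(1) errors, all other coefficients 0,
# unit total variance so fitted standardized coefficients estimate beta2.
sim_lmm_data <- function(seed, beta2 = -0.30, phi = 0.5, nsub = 40,
                         ndays = 28) {
  set.seed(seed)
  var_u <- 0.3
  var_e <- 1 - beta2^2 - var_u
  rows <- lapply(seq_len(nsub), function(j) {
    u <- rnorm(1, 0, sqrt(var_u))
    e <- as.numeric(stats::arima.sim(list(ar = phi), ndays,
                                     sd = sqrt(var_e * (1 - phi^2))))
    m10 <- rnorm(ndays)
    tibble::tibble(
      participant = j, cycle = 1L, enroll_day = seq_len(ndays),
      m10 = m10, sleep_min = rnorm(ndays), waso_min = rnorm(ndays),
      sri = rnorm(ndays), global_pain = rnorm(ndays),
      global_bfi = beta2 * m10 + u + e)
  })
  do.call(rbind, rows)
}
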