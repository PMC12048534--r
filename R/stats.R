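# Association layer: repeated-measures correlation (ANCOVA formulation),
# intra-person and partial correlations, AR(1) linear mixed models for daily
# symptoms, cycle-level Spearman associations and pre/post-surgery change.

#' Repeated-measures correlation
#'
#' Common within-subject association between two repeatedly measured
#' variables, from the analysis-of-covariance formulation with subject as a
#' factor and a common slope: `r` is the correlation of the within-subject
#' centered values with the slope's sign, `df = n_obs - n_subjects - 1`, and
#' the p-value comes from the F-ratio on `(1, df)`. Only pairwise-complete
#' rows are used; subjects with fewer than two complete pairs carry no
#' within-subject information and are dropped.
#'
#' @param x,y numeric vectors.
#' @param subject subject labels, same length.
#' @return list of class `rmcorr_result`: `r`, `df`, `p`, `n_subjects`,
#'   `n_obs`.
#' @export
rmcorr <- function(x, y, subject) {
  cc <- complete.cases(x, y, subject)
  x <- x[cc]; y <- y[cc]
  subject <- as.character(subject)[cc]
  tab <- table(subject)
  keep <- subject %in% names(tab)[tab >= 2]
  x <- x[keep]; y <- y[keep]; subject <- subject[keep]
  k <- length(unique(subject))
  n <- length(x)
  if (k < 2L) stop("rmcorr needs at least two subjects with >= 2 pairs",
                   call. = FALSE)
  xd <- x - ave(x, subject)
  yd <- y - ave(y, subject)
  ssx <- sum(xd^2); ssy <- sum(yd^2)
  if (ssx == 0 || ssy == 0) {
    stop("no within-subject variation in x or y", call. = FALSE)
  }
  r <- sum(xd * yd) / sqrt(ssx * ssy)
  df <- n - k - 1L
  fstat <- r^2 * df / (1 - r^2)
  p <- pf(fstat, 1, df, lower.tail = FALSE)
  structure(list(r = r, df = df, p = p, n_subjects = k, n_obs = n),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("rmcorr r = %.3f (df = %d, p = %.3g, %d subjects, %d obs)\n",
              x$r, x$df, x$p, x$n_subjects, x$n_obs))
  invisible(x)
}

#' Intra-person Pearson correlations
#'
#' Pearson correlation within each subject's own data, reported only for
#' subjects with at least `min_pairs` complete pairs; others are listed with
#' an exclusion reason (too few pairs, or constant input).
#'
#' @inheritParams rmcorr
#' @param min_pairs minimum complete pairs per subject.
#' @return tibble: `participant`, `n_pairs`, `r`, `included`, `reason`.
#' @export
intra_person_corr <- function(x, y, subject, min_pairs = 20) {
  subject <- as.character(subject)
  ids <- unique(subject)
  rows <- lapply(ids, function(id) {
    sel <- subject == id & complete.cases(x, y)
    nx <- x[sel]; ny <- y[sel]
    np <- length(nx)
    if (np < min_pairs) {
      return(tibble::tibble(participant = id, n_pairs = np, r = NA_real_,
                            included = FALSE, reason = "too few pairs"))
    }
    if (sd(nx) == 0 || sd(ny) == 0) {
      return(tibble::tibble(participant = id, n_pairs = np, r = NA_real_,
                            included = FALSE, reason = "constant input"))
    }
    tibble::tibble(participant = id, n_pairs = np, r = cor(nx, ny),
                   included = TRUE, reason = NA_character_)
  })
  do.call(rbind, rows)
}

#' Partial correlation matrix
#'
#' Partial correlation of every variable pair controlling for all remaining
#' variables, from the precision matrix: `r_ij.rest = -P_ij /
#' sqrt(P_ii * P_jj)` with `P` the inverse of the (Pearson or Spearman)
#' correlation matrix. Complete-case rows only.
#'
#' @param data numeric matrix or data frame (k columns, named).
#' @param method `"pearson"` or `"spearman"` (ranks first).
#' @return k x k matrix of partial correlations (unit diagonal).
#' @export
partial_corr <- function(data, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as.matrix(data)
  m <- m[complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (nrow(m) < k + 2) {
    stop("need at least k + 2 complete rows for k variables", call. = FALSE)
  }
  if (method == "spearman") m <- apply(m, 2, rank)
  R <- cor(m)
  P <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(P) || !all(is.finite(P))) {
    cors <- which(abs(R) > 0.999 & upper.tri(R), arr.ind = TRUE)
    culprits <- if (nrow(cors)) {
      paste(colnames(R)[cors[, 1]], colnames(R)[cors[, 2]],
            sep = " ~ ", collapse = ", ")
    } else "unknown"
    stop("singular correlation matrix; collinear variables: ", culprits,
         call. = FALSE)
  }
  D <- sqrt(diag(P))
  out <- -P / outer(D, D)
  diag(out) <- 1
  dimnames(out) <- dimnames(R)
  out
}

# Build lagged covariates within participant (and cycle): the lag of day i
# is the value at day i - 1, missing when that day is absent. First days of
# each cycle therefore drop out of complete-case model fits.
add_lag <- function(df, vars) {
  df <- df[order(df$participant, df$enroll_day), ]
  for (v in vars) {
    lagv <- rep(NA_real_, nrow(df))
    key <- paste(df$participant, df$cycle)
    prev <- match(paste(key, df$enroll_day - 1),
                  paste(key, df$enroll_day))
    ok <- !is.na(prev)
    lagv[ok] <- df[[v]][prev[ok]]
    df[[paste0(v, "_lag")]] <- lagv
  }
  df
}

#' AR(1) linear mixed model for daily symptoms
#'
#' Models the daily global BFI (fatigue) or global pain score as a linear
#' function of the other symptom score, same-day and previous-day M10,
#' same-night and previous-night sleep duration and WASO, and sleep
#' regularity, with a participant random intercept and a continuous-time
#' AR(1) residual correlation indexed by enrollment day (so correlation
#' decays as phi^(day gap) across missing days). All variables are
#' z-standardized over the included complete-case rows before fitting;
#' estimation is by REML via [nlme::lme()].
#'
#' @param daily data frame with columns `participant`, `cycle`,
#'   `enroll_day`, `global_bfi`, `global_pain`, `m10`, `sleep_min`,
#'   `waso_min`, `sri`.
#' @param response `"fatigue"` (global BFI) or `"pain"`.
#' @return list of class `lmm_fit`: `coefficients` (tibble with estimate,
#'   SE, df, t, p), `phi`, `sigma_resid`, `sigma_intercept`, `converged`,
#'   `n_obs`, `n_subjects`, and the underlying `model` (or `NULL`).
#' @export
fit_symptom_lmm <- function(daily, response = c("fatigue", "pain")) {
  response <- match.arg(response)
  df <- as.data.frame(daily)
  df <- add_lag(df, c("m10", "sleep_min", "waso_min"))
  resp_col <- if (response == "fatigue") "global_bfi" else "global_pain"
  other_col <- if (response == "fatigue") "global_pain" else "global_bfi"
  covars <- c(other_col, "m10", "m10_lag", "sleep_min", "sleep_min_lag",
              "waso_min", "waso_min_lag", "sri")
  use <- complete.cases(df[c(resp_col, covars, "participant",
                             "enroll_day")])
  df <- df[use, , drop = FALSE]
  if (length(unique(df$participant)) < 2L) {
    stop("need at least two subjects with complete rows", call. = FALSE)
  }
  zs <- function(v) (v - mean(v)) / sd(v)
  for (v in c(resp_col, covars)) df[[v]] <- zs(df[[v]])
  df$participant <- factor(df$participant)

  form <- stats::as.formula(paste(resp_col, "~",
                                  paste(covars, collapse = " + ")))
  fit <- tryCatch(
    nlme::lme(form, random = ~ 1 | participant,
              correlation = nlme::corCAR1(form = ~ enroll_day | participant),
              data = df, method = "REML",
              control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                         msMaxIter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = NULL, phi = NA_real_,
                          sigma_resid = NA_real_,
                          sigma_intercept = NA_real_,
                          converged = FALSE,
                          message = conditionMessage(fit),
                          n_obs = nrow(df),
                          n_subjects = nlevels(df$participant),
                          model = NULL),
                     class = "lmm_fit"))
  }
  tt <- summary(fit)$tTable
  coefs <- tibble::tibble(
    term = rownames(tt), estimate = tt[, "Value"],
    se = tt[, "Std.Error"], df = tt[, "DF"],
    t = tt[, "t-value"], p = tt[, "p-value"])
  phi <- as.numeric(coef(fit$modelStruct$corStruct,
                         unconstrained = FALSE))
  vc <- nlme::VarCorr(fit)
  structure(list(
    coefficients = coefs, phi = phi,
    sigma_resid = fit$sigma,
    sigma_intercept = suppressWarnings(
      as.numeric(vc["(Intercept)", "StdDev"])),
    converged = TRUE, message = NULL,
    n_obs = nrow(df), n_subjects = nlevels(df$participant),
    model = fit), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<lmm_fit> did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<lmm_fit> %d obs, %d subjects, AR(1) phi = %.3f\n",
              x$n_obs, x$n_subjects, x$phi))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Cycle-level Spearman associations
#'
#' Pairwise (and, given covariates, partial) Spearman correlations between
#' cycle- or participant-level summary variables, with a strength flag at
#' `|R| > strong_threshold`. No multiple-testing adjustment is applied (the
#' output metadata says so). Pairs with fewer than `min_n` complete rows are
#' missing.
#'
#' @param data wide data frame of summary variables (one row per cycle or
#'   participant).
#' @param vars columns to correlate pairwise.
#' @param covariates columns to control for (partial Spearman); `NULL` for
#'   plain pairwise correlations.
#' @param strong_threshold flag threshold on `|R|`.
#' @param min_n minimum complete rows per pair.
#' @return tibble `variable_x`, `variable_y`, `estimate`, `n`, `strong`,
#'   `partial`; attribute `multiple_testing_adjustment = "none"`.
#' @export
cycle_associations <- function(data, vars, covariates = NULL,
                               strong_threshold = 0.3, min_n = 4) {
  data <- as.data.frame(data)
  pairs <- utils::combn(vars, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    vx <- pairs[1, i]; vy <- pairs[2, i]
    cols <- c(vx, vy, covariates)
    sub <- data[cols]
    sub <- sub[complete.cases(sub), , drop = FALSE]
    n <- nrow(sub)
    est <- NA_real_
    if (n >= max(min_n, length(cols) + 2 * !is.null(covariates))) {
      if (is.null(covariates)) {
        est <- suppressWarnings(cor(sub[[vx]], sub[[vy]],
                                    method = "spearman"))
      } else {
        pm <- tryCatch(partial_corr(sub, method = "spearman"),
                       error = function(e) NULL)
        if (!is.null(pm)) est <- pm[vx, vy]
      }
    }
    tibble::tibble(variable_x = vx, variable_y = vy, estimate = est,
                   n = n, strong = !is.na(est) & abs(est) > strong_threshold,
                   partial = !is.null(covariates))
  })
  out <- do.call(rbind, rows)
  attr(out, "multiple_testing_adjustment") <- "none"
  out
}

#' Min-max scaling over a pooled sample
#'
#' @param x numeric; scaled to `[0, 1]` over its non-missing range. A
#'   constant input returns all-missing (no defined scale).
#' @export
minmax_scale <- function(x) {
  lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
  if (!is.finite(lo) || !is.finite(hi) || hi == lo) {
    return(rep(NA_real_, length(x)))
  }
  (x - lo) / (hi - lo)
}

#' Changes following surgical intervention
#'
#' For each measure: daily values are min-max scaled across all daily data
#' from all participants; each participant's change is the mean of the
#' scaled values over the 10 days immediately post-surgery minus the mean
#' over the pre-surgery baseline cycle. Participants with fewer than
#' `min_points` non-missing post-operative values are excluded with a
#' reason. The cohort post-operative trajectory uses only days covered by
#' at least `coverage` of the included participants. Cycle-level raw-mean
#' deltas (follow-up minus baseline cycle) support the longer-term
#' comparison.
#'
#' @param daily data frame: `participant`, `date`, `cycle`, plus measure
#'   columns.
#' @param manifest data frame: `participant`, `surgery_date` (NA = no
#'   surgery; such participants are ignored).
#' @param vars measure columns.
#' @param baseline_cycle pre-surgery cycle index.
#' @param followup_cycle cycle index for the cycle-level delta.
#' @param post_days length of the post-operative window, days.
#' @param min_points minimum post-operative data points for inclusion.
#' @param coverage minimum participant coverage for trajectory days.
#' @return list of class `surgical_change`: `deltas`, `trajectory`,
#'   `cycle_deltas`.
#' @export
surgical_change <- function(daily, manifest, vars, baseline_cycle = 1,
                            followup_cycle = 3, post_days = 10,
                            min_points = 3, coverage = 0.5) {
  daily <- as.data.frame(daily)
  man <- unique(as.data.frame(manifest)[c("participant", "surgery_date")])
  man <- man[!is.na(man$surgery_date), , drop = FALSE]
  scaled <- daily
  for (v in vars) scaled[[v]] <- minmax_scale(daily[[v]])

  deltas <- list(); traj <- list(); cyc <- list()
  for (v in vars) {
    per <- lapply(seq_len(nrow(man)), function(i) {
      p <- man$participant[i]; sdate <- as.Date(man$surgery_date[i])
      rows <- scaled[scaled$participant == p, , drop = FALSE]
      post <- rows[rows$date >= sdate + 1 &
                     rows$date <= sdate + post_days, , drop = FALSE]
      base <- rows[rows$cycle == baseline_cycle, , drop = FALSE]
      n_post <- sum(!is.na(post[[v]]))
      n_base <- sum(!is.na(base[[v]]))
      incl <- n_post >= min_points && n_base > 0
      tibble::tibble(
        participant = p, variable = v,
        baseline_mean = if (n_base) mean(base[[v]], na.rm = TRUE)
                        else NA_real_,
        post_mean = if (n_post) mean(post[[v]], na.rm = TRUE) else NA_real_,
        delta = if (incl) mean(post[[v]], na.rm = TRUE) -
          mean(base[[v]], na.rm = TRUE) else NA_real_,
        n_post = n_post, included = incl,
        reason = if (incl) NA_character_ else if (n_post < min_points)
          sprintf("fewer than %d post-operative points", min_points)
        else "no baseline data")
    })
    per <- do.call(rbind, per)
    deltas[[v]] <- per
    included <- per$participant[per$included]
    if (length(included)) {
      tr <- lapply(seq_len(post_days), function(dd) {
        vals <- vapply(included, function(p) {
          sdate <- as.Date(man$surgery_date[man$participant == p][1])
          r <- scaled[scaled$participant == p &
                        scaled$date == sdate + dd, v]
          if (length(r)) r[[1]] else NA_real_
        }, numeric(1))
        cov <- mean(!is.na(vals))
        tibble::tibble(variable = v, post_day = dd,
                       mean = if (cov >= coverage)
                         mean(vals, na.rm = TRUE) else NA_real_,
                       n = sum(!is.na(vals)), coverage = cov)
      })
      traj[[v]] <- do.call(rbind, tr)
    }
    cd <- lapply(man$participant, function(p) {
      rows <- daily[daily$participant == p, , drop = FALSE]
      b <- mean(rows[[v]][rows$cycle == baseline_cycle], na.rm = TRUE)
      f <- mean(rows[[v]][rows$cycle == followup_cycle], na.rm = TRUE)
      tibble::tibble(participant = p, variable = v,
                     baseline = b, followup = f, delta = f - b)
    })
    cyc[[v]] <- do.call(rbind, cd)
  }
  structure(list(deltas = do.call(rbind, deltas),
                 trajectory = do.call(rbind, traj),
                 cycle_deltas = do.call(rbind, cyc)),
            class = "surgical_change")
}
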