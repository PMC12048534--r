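# Association layer: rmcorr, intra-person and partial correlations, the
# AR(1) mixed model, cycle-level associations and surgical change.

test_that("rmcorr handles perfect within-subject relations", {
  x <- rep(1:10, 3)
  off <- rep(c(0, 5, 11), each = 10)
  r <- rmcorr(x, x + off, rep(1:3, each = 10))
  expect_equal(r$r, 1, tolerance = 1e-12)
  rn <- rmcorr(x, -x + off, rep(1:3, each = 10))
  expect_equal(rn$r, -1, tolerance = 1e-12)
  expect_equal(rn$df, 30 - 3 - 1)
})

test_that("rmcorr matches the brute-force ANCOVA oracle", {
  set.seed(60)
  for (i in 1:12) {
    ns <- sample(3:10, 1)
    no <- sample(5:30, 1)
    subj <- rep(seq_len(ns), each = no)
    x <- rnorm(ns * no) + rep(rnorm(ns, sd = 2), each = no)
    y <- 0.4 * x + rnorm(ns * no) + rep(rnorm(ns, sd = 2), each = no)
    if (i %% 3 == 0) x[sample(length(x), 5)] <- NA
    got <- rmcorr(x, y, subj)
    want <- bf_rmcorr(x, y, subj)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  expect_error(rmcorr(rep(1, 20), rnorm(20), rep(1:2, each = 10)),
               "within-subject")
})

test_that("intra-person correlations apply the 20-pair rule", {
  set.seed(61)
  subj <- rep(c("a", "b", "c"), c(19, 25, 25))
  x <- rnorm(69); y <- rnorm(69)
  y[subj == "b"] <- 2 * x[subj == "b"]
  x[subj == "c"] <- 1  # constant
  res <- intra_person_corr(x, y, subj)
  expect_false(res$included[res$participant == "a"])
  expect_equal(res$reason[res$participant == "a"], "too few pairs")
  expect_equal(res$r[res$participant == "b"], 1, tolerance = 1e-12)
  expect_equal(res$reason[res$participant == "c"], "constant input")

  # textbook-formula oracle
  sel <- subj == "b"
  xb <- x[sel]; yb <- rnorm(25)
  r_direct <- sum((xb - mean(xb)) * (yb - mean(yb))) /
    sqrt(sum((xb - mean(xb))^2) * sum((yb - mean(yb))^2))
  expect_equal(intra_person_corr(xb, yb, rep("b", 25))$r, r_direct,
               tolerance = 1e-12)
})

test_that("partial correlations match the closed forms", {
  set.seed(62)
  # two variables: partial equals pairwise
  m2 <- cbind(x = rnorm(50), y = rnorm(50))
  expect_equal(partial_corr(m2)["x", "y"], cor(m2)[1, 2],
               tolerance = 1e-12)

  # three variables: first-order recursion formula
  m3 <- cbind(x = rnorm(80), y = rnorm(80), z = rnorm(80))
  m3[, "x"] <- m3[, "x"] + 0.5 * m3[, "z"]
  m3[, "y"] <- m3[, "y"] + 0.5 * m3[, "z"]
  R <- cor(m3)
  want <- bf_partial3(R["x", "y"], R["x", "z"], R["z", "y"])
  expect_equal(partial_corr(m3)["x", "y"], want, tolerance = 1e-12)

  # spurious correlation via a confounder vanishes after control
  set.seed(63)
  z <- rnorm(10000)
  m <- cbind(x = z + rnorm(10000), y = z + rnorm(10000), z = z)
  expect_gt(cor(m)["x", "y"], 0.3)
  expect_lt(abs(partial_corr(m)["x", "y"]), 0.05)

  # collinear input errors with the culprit names
  bad <- cbind(a = rnorm(30), b = 0, c = rnorm(30))
  bad[, "b"] <- bad[, "a"]
  expect_error(partial_corr(bad), "a ~ b")
  expect_error(partial_corr(m3[1:4, ]), "complete rows")
})

test_that("the symptom mixed model builds lags within participant-cycle", {
  d <- tibble::tibble(
    participant = rep(1:2, each = 6),
    cycle = rep(c(1L, 1L, 1L, 2L, 2L, 2L), 2),
    enroll_day = rep(c(1:3, 31:33), 2),
    m10 = as.numeric(1:12), sleep_min = rnorm(12), waso_min = rnorm(12),
    sri = rnorm(12), global_pain = rnorm(12), global_bfi = rnorm(12))
  dl <- actisym:::add_lag(as.data.frame(d), "m10")
  # first day of each cycle has no lag
  expect_true(all(is.na(dl$m10_lag[dl$enroll_day %in% c(1, 31)])))
  expect_equal(dl$m10_lag[dl$enroll_day == 2 & dl$participant == 1], 1)
  expect_equal(dl$m10_lag[dl$enroll_day == 33 & dl$participant == 2], 11)
})

test_that("the AR(1) mixed model recovers phi and flags convergence", {
  f <- fit_symptom_lmm(sim_lmm_data(7, beta2 = -0.3, phi = 0.5, nsub = 30,
                                    ndays = 25), "fatigue")
  expect_true(f$converged)
  expect_lt(abs(f$phi - 0.5), 0.15)
  b2 <- f$coefficients$estimate[f$coefficients$term == "m10"]
  expect_lt(abs(b2 + 0.3), 3 * f$coefficients$se[f$coefficients$term ==
                                                   "m10"] + 0.05)
  expect_true(all(c("global_pain", "m10", "m10_lag", "sleep_min_lag",
                    "waso_min_lag", "sri") %in% f$coefficients$term))
})

test_that("cycle associations flag strength and respect minimum n", {
  set.seed(64)
  n <- 24
  d <- tibble::tibble(a = rnorm(n))
  d$b <- exp(d$a)               # monotone transform: Spearman 1
  d$c <- rnorm(n)
  d$c[1:22] <- NA               # only 2 complete rows for pairs with c
  res <- cycle_associations(d, c("a", "b", "c"))
  ab <- res[res$variable_x == "a" & res$variable_y == "b", ]
  expect_equal(ab$estimate, 1)
  expect_true(ab$strong)
  ac <- res[res$variable_x == "a" & res$variable_y == "c", ]
  expect_true(is.na(ac$estimate))
  expect_equal(attr(res, "multiple_testing_adjustment"), "none")

  # partial variant controls for covariates
  z <- rnorm(200)
  dp <- tibble::tibble(x = z + rnorm(200), y = z + rnorm(200), z = z)
  plain <- cycle_associations(dp, c("x", "y"))
  ctrl <- cycle_associations(dp, c("x", "y"), covariates = "z")
  expect_gt(abs(plain$estimate), abs(ctrl$estimate))
  expect_true(ctrl$partial)
})

test_that("surgical change applies scaling, inclusion and coverage rules", {
  set.seed(65)
  dates <- as.Date("2024-03-04") + 0:55
  mk_p <- function(p, drop_after, n_post_obs) {
    v <- c(rnorm(28, 10, 0.5), rnorm(28, drop_after, 0.5))
    d <- tibble::tibble(participant = p, date = dates,
                        cycle = rep(1:2, each = 28), v = v)
    post <- d$date > as.Date("2024-03-31") &
      d$date <= as.Date("2024-03-31") + 10
    keep_idx <- which(post)[seq_len(min(n_post_obs, sum(post)))]
    d$v[post][!(which(post) %in% keep_idx)] <- NA
    d
  }
  daily <- rbind(mk_p("a", 4, 10), mk_p("b", 5, 3), mk_p("c", 6, 2))
  man <- tibble::tibble(participant = c("a", "b", "c"),
                        surgery_date = as.Date("2024-03-31"))
  sc <- surgical_change(daily, man, "v", baseline_cycle = 1,
                        followup_cycle = 2)
  dl <- sc$deltas
  expect_true(all(dl$delta[dl$participant %in% c("a", "b")] < 0))
  expect_false(dl$included[dl$participant == "c"])
  expect_match(dl$reason[dl$participant == "c"], "post-operative")

  # trajectory days covered by fewer than 50% of included participants
  # (a has 10 post days, b has 3: days 4..10 covered by 1 of 2) are blank
  tr <- sc$trajectory
  expect_true(all(is.na(tr$mean[tr$coverage < 0.5])))
  expect_true(any(!is.na(tr$mean)))

  # scaled values live in [0, 1]
  expect_true(all(dl$baseline_mean >= 0 & dl$baseline_mean <= 1,
                  na.rm = TRUE))

  # deltas invariant to affine rescaling of the raw measure
  daily2 <- daily; daily2$v <- 100 + 7 * daily2$v
  sc2 <- surgical_change(daily2, man, "v", baseline_cycle = 1,
                         followup_cycle = 2)
  expect_equal(sc2$deltas$delta, dl$delta, tolerance = 1e-12)

  # constant measure has no defined scale
  daily3 <- daily; daily3$v <- 5
  sc3 <- surgical_change(daily3, man, "v", followup_cycle = 2)
  expect_true(all(is.na(sc3$deltas$delta)))
})
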