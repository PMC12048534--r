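# Two-pass temperature + movement non-wear detection.

test_that("T0 is the larger of the floor and the 5th percentile", {
  expect_equal(compute_t0(rep(30, 100)), 30)
  expect_equal(compute_t0(rep(20, 100)), 26)
  set.seed(10)
  x <- runif(20000, 25, 35)
  expect_equal(compute_t0(x), max(26, quantile(x, 0.05, type = 7)),
               ignore_attr = TRUE)
  expect_error(compute_t0(rep(NA_real_, 5)), "temperature")
})

test_that("T1 follows the capped sd rule with percentile and short-wear overrides", {
  # worn temps mean 31 sd 1 over 10 days; all-readings p5 = 27
  set.seed(11)
  worn <- rnorm(10 * 1440, 31, 1)
  worn <- (worn - mean(worn)) / sd(worn) + 31  # exact mean 31, sd 1
  cold <- rep(27, 40)  # tiny cold tail keeps p5(all) at 27
  ts <- c(worn, cold)
  p1 <- rep(c(FALSE, TRUE), c(length(worn), length(cold)))
  p5 <- unname(quantile(ts, 0.05, type = 7))
  t1 <- compute_t1(ts, p1)
  # min(31 - 1, 24) = 24, then the 5th percentile (> 24) overrides
  expect_gt(p5, 24)
  expect_equal(t1, p5)

  # fewer than 3 worn days: T1 fixed at 24
  expect_equal(compute_t1(rep(31, 2 * 1440), rep(FALSE, 2 * 1440)), 24)

  # mean 30 sd 8, p5(all) = 20 < 22: stays min(22, 24) = 22
  set.seed(12)
  worn <- rnorm(5 * 1440, 30, 8)
  worn <- (worn - mean(worn)) / sd(worn) * 8 + 30
  ts2 <- c(worn, rep(19, 2000))  # cold mass pulls p5 below 22
  p1b <- rep(c(FALSE, TRUE), c(length(worn), 2000))
  expect_lt(unname(quantile(ts2, 0.05, type = 7)), 22)
  expect_equal(compute_t1(ts2, p1b), 22)
})

test_that("pass 1 detects long cold-still runs and fuses close pairs", {
  # warm and active: nothing
  ep <- make_epoch_frame(6 * 60, t_smooth = 30, rocam = 0.1)
  expect_equal(nrow(detect_long_nonwear(ep, 26)), 0)

  # one 120-min cold still block
  n <- 10 * 60
  ts <- rep(31, n); rc <- rep(0.1, n)
  ts[241:360] <- 22; rc[241:360] <- 0.002
  ep <- make_epoch_frame(n, t_smooth = ts, rocam = rc)
  iv <- detect_long_nonwear(ep, 26)
  expect_equal(nrow(iv), 1)
  expect_lte(abs(as.numeric(difftime(iv$start[1],
                                     ep$minute$time[241], units = "mins"))), 5)
  expect_lte(abs(as.numeric(difftime(iv$end[1],
                                     ep$minute$time[360] + 60,
                                     units = "mins"))), 5)

  # two 100-min runs separated by 10 min fuse into one
  ts <- rep(31, n); rc <- rep(0.1, n)
  ts[101:200] <- 22; rc[101:200] <- 0.002
  ts[211:310] <- 22; rc[211:310] <- 0.002
  ep <- make_epoch_frame(n, t_smooth = ts, rocam = rc)
  iv <- detect_long_nonwear(ep, 26)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start[1], ep$minute$time[101])
  expect_equal(iv$end[1], ep$minute$time[310] + 60)

  # a still-but-warm run is not a candidate
  ts <- rep(31, n); rc <- rep(0.002, n)
  ep <- make_epoch_frame(n, t_smooth = ts, rocam = rc)
  expect_equal(nrow(detect_long_nonwear(ep, 26)), 0)
})

test_that("pass 2 keeps only 15-90 min runs with a 2-degree start-end drop", {
  n <- 8 * 60
  none <- tibble::tibble(start = t_origin[0], end = t_origin[0])

  # 30-min still block with flat (cold) temperature: rejected by drop rule
  ts <- rep(31, n); rc <- rep(0.1, n)
  ts[241:270] <- 22; rc[241:270] <- 0.002
  ep <- make_epoch_frame(n, t_smooth = ts, rocam = rc)
  expect_equal(nrow(detect_short_nonwear(ep, 24, none)), 0)

  # 30-min block falling 28 -> 24: kept
  ts <- rep(31, n); rc <- rep(0.1, n)
  ts[241:270] <- seq(23.9, 20, length.out = 30)  # below T1 and falling
  rc[241:270] <- 0.002
  ep <- make_epoch_frame(n, t_smooth = ts, rocam = rc)
  iv <- detect_short_nonwear(ep, 24, none)
  expect_equal(nrow(iv), 1)

  # 12-min block meeting all other criteria: below the 15-min minimum
  ts <- rep(31, n); rc <- rep(0.1, n)
  ts[241:252] <- seq(23.9, 20, length.out = 12); rc[241:252] <- 0.002
  ep <- make_epoch_frame(n, t_smooth = ts, rocam = rc)
  expect_equal(nrow(detect_short_nonwear(ep, 24, none)), 0)

  # a run of exactly 90 min belongs to pass 1, not pass 2
  ts <- rep(31, n); rc <- rep(0.1, n)
  ts[121:210] <- seq(23.9, 18, length.out = 90); rc[121:210] <- 0.002
  ep <- make_epoch_frame(n, t_smooth = ts, rocam = rc)
  expect_equal(nrow(detect_short_nonwear(ep, 24, none)), 0)
  expect_equal(nrow(detect_long_nonwear(ep, 26)), 1)
})

test_that("wear mask covers the recording with consistent provenance", {
  n <- 4 * 1440
  ts <- rep(31, n); rc <- rep(0.1, n)
  ts[1000:1179] <- 21; rc[1000:1179] <- 0.002  # 180-min pass-1 block
  ep <- make_epoch_frame(n, t_smooth = ts, rocam = rc)
  mask <- wear_mask(ep)
  expect_equal(nrow(mask), n)
  expect_setequal(unique(mask$provenance[!mask$worn]),
                  c("pass1"))
  expect_true(all(mask$worn[mask$provenance == "worn"]))
  # idempotence
  mask2 <- wear_mask(ep)
  expect_identical(mask$worn, mask2$worn)

  # fully worn day: wear fraction 1
  ep2 <- make_epoch_frame(1440, t_smooth = 31, rocam = 0.1)
  wf <- wear_fraction(wear_mask(ep2), "midnight")
  expect_equal(wf$wear_frac, 1)
})

test_that("pass-2 intervals never overlap pass-1 and rocam threshold is monotone", {
  set.seed(13)
  ev <- fixture_nonwear_events(7)
  cfg <- cohort_config(n_participants = 1, days_per_cycle = 7,
                       n_cycles = 1, nonwear_events = ev, seed = 13)
  p <- simulate_participant(cfg, 1)
  ep <- epochize(p$recording)
  mask <- wear_mask(ep)
  iv <- attr(mask, "intervals")
  p1 <- iv[iv$pass == "pass1", ]; p2 <- iv[iv$pass == "pass2", ]
  if (nrow(p1) && nrow(p2)) {
    for (i in seq_len(nrow(p2))) {
      expect_false(any(p2$start[i] < p1$end & p2$end[i] > p1$start))
    }
  }
  # raising the rocam threshold can only grow the non-wear set
  lo <- wear_mask(ep, nonwear_config(rocam_thresh = 0.01))
  hi <- wear_mask(ep, nonwear_config(rocam_thresh = 0.05))
  expect_true(all(!hi$worn[!lo$worn]))
})

test_that("detector recovers injected non-wear on a synthetic recording", {
  set.seed(14)
  ev <- fixture_nonwear_events(7)
  cfg <- cohort_config(n_participants = 1, days_per_cycle = 7,
                       n_cycles = 1, nonwear_events = ev, seed = 14)
  p <- simulate_participant(cfg, 1)
  mask <- wear_mask(epochize(p$recording))
  truth_nw <- mask$time >= p$truth$nonwear_intervals$start[1] &
    mask$time < p$truth$nonwear_intervals$end[1]
  truth_all <- rep(FALSE, nrow(mask))
  for (i in seq_len(nrow(p$truth$nonwear_intervals))) {
    truth_all <- truth_all |
      (mask$time >= p$truth$nonwear_intervals$start[i] &
         mask$time < p$truth$nonwear_intervals$end[i])
  }
  det <- !mask$worn
  sens <- sum(det & truth_all) / sum(truth_all)
  spec <- sum(!det & !truth_all) / sum(!truth_all)
  expect_gte((sens + spec) / 2, 0.95)
})
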