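# The cohort generator: determinism, scale bounds, coupling, non-wear
# injection physics, phenotypes.

test_that("identical config and seed reproduce identical bundles", {
  cfg <- cohort_config(n_participants = 2, days_per_cycle = 2, n_cycles = 1,
                       seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$participants[[1]]$recording$data,
                   b$participants[[1]]$recording$data)
  expect_identical(a$diary, b$diary)
  expect_identical(a$ehp30, b$ehp30)
  expect_identical(a$manifest, b$manifest)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(n_cycles = 4), "n_cycles")
  expect_error(cohort_config(coupling_fatigue_activity = 1.2), "coupling")
  expect_error(cohort_config(prom_missing_rate = 1.4), "missing")
  expect_error(cohort_config(surgery_day = 40, days_per_cycle = 28,
                             n_cycles = 1), "outside the recording span")
  expect_error(cohort_config(phenotype = "bogus"), "phenotype")
})

test_that("generated item scores always respect their scale bounds", {
  for (s in 1:4) {
    cfg <- cohort_config(n_participants = 3, days_per_cycle = 28,
                         phenotype = c("cyclical", "constant-severe",
                                       "flare"),
                         seed = s)
    b <- simulate_cohort(cfg, raw = FALSE)
    expect_true(all(b$diary$pain_avg %in% 1:10))
    expect_true(all(b$diary$pain_worst %in% 1:10))
    bfi <- as.matrix(b$diary[paste0("bfi_q", 1:9)])
    expect_true(all(bfi %in% 0:10))
    items <- as.matrix(b$ehp30[sprintf("item_%02d", 1:30)])
    expect_true(all(items %in% 0:4))
  }
})

test_that("zero noise with zero coupling yields constant truth", {
  cfg <- cohort_config(n_participants = 1, days_per_cycle = 14,
                       phenotype = "constant-severe",
                       coupling_fatigue_activity = 0, noise_scale = 0,
                       seed = 1)
  p <- simulate_participant(cfg, 1, raw = FALSE)
  expect_equal(diff(range(p$truth$daily$fatigue)), 0)
  expect_equal(diff(range(p$truth$daily$activity)), 0)
  expect_equal(p$truth$daily$fatigue[1], 7)  # constant-severe baseline
})

test_that("seed sweep varies missingness but not the manifest structure", {
  masks <- list()
  for (s in 1:5) {
    cfg <- cohort_config(n_participants = 1, days_per_cycle = 28,
                         prom_missing_rate = 0.3, seed = s)
    b <- simulate_cohort(cfg, raw = FALSE)
    masks[[s]] <- b$diary$assoc_date
    expect_equal(names(b$manifest),
                 c("participant", "cycle", "start_date", "end_date",
                   "surgery_date", "wrist"))
    expect_equal(nrow(b$manifest), 1)
  }
  expect_gt(length(unique(sapply(masks, paste, collapse = ","))), 1)
})

test_that("injected non-wear freezes movement and cools the device", {
  cfg <- cohort_config(n_participants = 1, days_per_cycle = 1, n_cycles = 1,
                       nonwear_events = data.frame(start_min = numeric(),
                                                   duration_min = numeric()),
                       seed = 3)
  p <- simulate_participant(cfg, 1)
  rec <- p$recording

  # empty interval list: identity
  same <- inject_nonwear(rec, NULL)
  expect_identical(same$data, rec$data)

  iv <- tibble::tibble(start = as.POSIXct("2024-03-04 14:00:00", tz = "UTC"),
                       end = as.POSIXct("2024-03-04 16:00:00", tz = "UTC"))
  out <- inject_nonwear(rec, iv, ambient = 21)
  sel <- out$data$timestamp >= iv$start & out$data$timestamp < iv$end
  # acceleration variance at the sensor noise floor
  expect_lt(sd(out$data$ax_g[sel]), 0.005)
  # minute-level smoothed temperature below 24 by interval end
  last10 <- out$data$temp_c[sel][sum(sel) - (599:0)]
  expect_lt(mean(last10), 24)
  # untouched outside the interval and its rewarming tail
  before <- out$data$timestamp < iv$start
  expect_identical(out$data$ax_g[before], rec$data$ax_g[before])
  expect_identical(out$data$temp_c[before], rec$data$temp_c[before])

  # overlapping intervals merge with a warning
  iv2 <- tibble::tibble(
    start = as.POSIXct(c("2024-03-04 14:00:00", "2024-03-04 15:00:00"),
                       tz = "UTC"),
    end = as.POSIXct(c("2024-03-04 15:30:00", "2024-03-04 16:30:00"),
                     tz = "UTC"))
  expect_warning(inject_nonwear(rec, iv2), "merged")
  # intervals outside the recording are rejected
  iv3 <- tibble::tibble(start = as.POSIXct("2024-03-06 00:00:00",
                                           tz = "UTC"),
                        end = as.POSIXct("2024-03-06 01:00:00", tz = "UTC"))
  expect_error(inject_nonwear(rec, iv3), "within the recording")
})

test_that("a 10-min removal is labeled in truth but below the detector floor", {
  ev <- data.frame(start_min = 14 * 60, duration_min = 10)
  cfg <- cohort_config(n_participants = 1, days_per_cycle = 1, n_cycles = 1,
                       nonwear_events = ev, seed = 4)
  p <- simulate_participant(cfg, 1)
  expect_equal(nrow(p$truth$nonwear_intervals), 1)
  mask <- wear_mask(epochize(p$recording))
  nw <- attr(mask, "intervals")
  overlaps <- nrow(nw) > 0 &&
    any(nw$start < p$truth$nonwear_intervals$end[1] &
          nw$end > p$truth$nonwear_intervals$start[1])
  expect_false(overlaps)
})

test_that("during injected non-wear the stillness statistic is under the
           detector threshold", {
  set.seed(5)
  ev <- data.frame(start_min = c(10 * 60, 30 * 60), duration_min = c(120, 90))
  cfg <- cohort_config(n_participants = 1, days_per_cycle = 2, n_cycles = 1,
                       nonwear_events = ev, seed = 5)
  p <- simulate_participant(cfg, 1)
  ep <- epochize(p$recording)
  nw <- actisym:::in_intervals(ep$minute$time, p$truth$nonwear_intervals)
  expect_true(all(ep$minute$rocam[nw] < 0.025))
})

test_that("post-surgical truth drops at surgery then recovers monotonically", {
  cfg <- cohort_config(n_participants = 1, days_per_cycle = 28, n_cycles = 2,
                       phenotype = "post-surgical", surgery_day = 29,
                       coupling_fatigue_activity = 0,
                       noise_scale = 0, seed = 6)
  p <- simulate_participant(cfg, 1, raw = FALSE)
  act <- p$truth$daily$activity
  expect_lt(act[29], 0.5 * act[28])
  post <- act[29:56]
  expect_true(all(diff(post) >= -1e-12))
  expect_lt(post[28], act[28] + 1e-9)
})

test_that("simulate_cohort of one yields one bundle and one manifest row", {
  cfg <- cohort_config(n_participants = 1, days_per_cycle = 2, seed = 9)
  b <- simulate_cohort(cfg, raw = FALSE)
  expect_length(b$participants, 1)
  expect_equal(nrow(b$manifest), 1)
})

test_that("cohort files round-trip through the plain-text writers", {
  cfg <- cohort_config(n_participants = 1, days_per_cycle = 1, seed = 10)
  b <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "raw_p001.csv")))
  expect_true(file.exists(file.path(dir, "truth_p001.json")))
  rec <- read_raw(file.path(dir, "raw_p001.csv"), 1, 1)
  expect_equal(nrow(rec$data), nrow(b$participants[[1]]$recording$data))
  expect_equal(rec$data$ax_g, b$participants[[1]]$recording$data$ax_g,
               tolerance = 1e-6)
})
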