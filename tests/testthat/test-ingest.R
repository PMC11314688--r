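# Calibration, ENMO epochs, non-wear detection, imputation, inclusion
# rules.

test_that("a perfectly calibrated still signal yields the identity", {
  rec <- still_recording(c(0, 0, 1), secs = 300)
  cal <- autocalibrate(rec)
  expect_equal(cal$offset, c(0, 0, 0), tolerance = 1e-8)
  expect_equal(cal$gain, c(1, 1, 1), tolerance = 1e-8)
  expect_lt(cal$post_error, 1e-6)
})

test_that("planted offsets and gains are recovered within 1e-3", {
  off <- c(0.05, -0.03, 0.02); gn <- c(1.02, 0.98, 1.01)
  sim <- simulate_still_recording(offset = off, gain = gn, seed = 3)
  cal <- autocalibrate(sim$rec)
  expect_true(cal$converged)
  expect_lt(max(abs(cal$offset - off)), 1e-3)
  expect_lt(max(abs(cal$gain - gn)), 1e-3)
})

test_that("calibration never increases the still-point error", {
  for (seed in 1:5) {
    sim <- simulate_still_recording(
      offset = runif(3, -0.05, 0.05), gain = runif(3, 0.97, 1.03),
      n_orientations = 15, seed = seed)
    cal <- autocalibrate(sim$rec)
    expect_lte(cal$post_error, cal$pre_error)
  }
})

test_that("ENMO epochs follow the closed forms", {
  # |v| = 1 g exactly -> 0 mg
  rec <- still_recording(c(0, 0, 1), secs = 60)
  expect_equal(compute_enmo_epochs(rec)$enmo, rep(0, 12))
  # |v| = 1.1 g -> 100 mg
  rec <- still_recording(c(0, 0, 1.1), secs = 60)
  expect_equal(compute_enmo_epochs(rec)$enmo, rep(100, 12),
               tolerance = 1e-10)
  # |v| = 0.9 g -> 0 mg, not -100 (negatives truncated per sample)
  rec <- still_recording(c(0, 0, 0.9), secs = 60)
  expect_equal(compute_enmo_epochs(rec)$enmo, rep(0, 12))
})

test_that("vectorised ENMO equals the naive per-sample loop", {
  set.seed(8)
  d <- matrix(rnorm(3 * 20 * 60, sd = 0.4), ncol = 3)
  d[, 3] <- d[, 3] + 1
  rec <- triaxial_recording("T", d, 20)
  got <- compute_enmo_epochs(rec)$enmo
  expect_equal(got, oracle_enmo_epochs(d, 20), tolerance = 1e-9)
})

test_that("non-integer samples per epoch are rejected", {
  rec <- triaxial_recording("T", matrix(rnorm(33), ncol = 3), 1.1)
  expect_error(compute_enmo_epochs(rec), "integer number of samples")
})

test_that("an absolutely constant stretch is detected as one non-wear segment", {
  s <- activity_schedule(nonwear_segments = data.frame(start = "13:00",
                                                       duration = 120))
  gr <- generate_participant(s, days = 1, mode = "raw", seed = 5)
  seg <- detect_nonwear(gr$data)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_sec, 13 * 3600)
  expect_equal(seg$end_sec, 15 * 3600)
})

test_that("a planted 90-min gap is recovered with at least 80% overlap", {
  s <- activity_schedule(nonwear_segments = data.frame(start = "13:00",
                                                       duration = 90))
  for (seed in c(9, 19)) {
    gr <- generate_participant(s, days = 1, mode = "raw", seed = seed)
    seg <- detect_nonwear(gr$data)
    truth <- gr$truth$nonwear
    ov <- sum(pmax(0, pmin(seg$end_sec, truth$end_sec[1]) -
                     pmax(seg$start_sec, truth$start_sec[1])))
    expect_gte(ov / (truth$end_sec[1] - truth$start_sec[1]), 0.8)
  }
})

test_that("vigorous worn signal produces no non-wear segments", {
  gv <- generate_participant(activity_schedule(), days = 1, mode = "raw",
                             seed = 10)
  expect_equal(nrow(detect_nonwear(gv$data)), 0)
})

test_that("the epoch-only surrogate recovers a planted gap and says so", {
  s <- activity_schedule(nonwear_segments = data.frame(start = "13:00",
                                                       duration = 90))
  ge <- generate_participant(s, days = 1, seed = 9)
  ge$data$flag[] <- "wear"
  expect_message(seg <- detect_nonwear(ge$data), "surrogate")
  expect_equal(attr(seg, "method"), "enmo_surrogate")
  expect_equal(seg$start_sec, 13 * 3600)
  expect_equal(seg$end_sec, 14.5 * 3600)
})

test_that("imputation is the identity on fully worn series", {
  x <- day_series(runif(17280, 0, 50))
  expect_identical(impute_nonwear(x)$enmo, x$enmo)
})

test_that("imputation uses the mean of the same slot on other days", {
  # 4 days; slot at 10:00:00 carries 40/50/60 on days 1,2,4; day 3 non-wear
  n <- 4 * 17280
  enmo <- rep(10, n)
  slot <- 10 * 720 + 1
  at <- slot + (0:3) * 17280
  enmo[at] <- c(40, 50, 10, 60)
  flag <- rep("wear", n)
  flag[at[3]] <- "nonwear"
  x <- epoch_series("T", enmo, flag)
  out <- impute_nonwear(x)
  expect_equal(out$enmo[at[3]], 50)
  expect_equal(out$flag[at[3]], "imputed")
  # conservation: imputed value equals the mean of valid same-slot values
  expect_equal(out$enmo[at[3]], mean(c(40, 50, 60)))
})

test_that("slots unworn on every day stay unimputed and exclude the participant", {
  n <- 4 * 17280
  flag <- rep("wear", n)
  # 02:00-02:15 non-wear on all four days
  for (d in 0:3) {
    idx <- d * 17280 + (2 * 720 + 1):(2.25 * 720)
    flag[idx] <- "nonwear"
  }
  x <- epoch_series("T", rep(20, n), flag)
  out <- impute_nonwear(x)
  expect_true(any(out$flag == "nonwear"))
  v <- validate_wear(out)
  expect_false(v$included)
  expect_equal(v$exclusion_reason, "slot_coverage")
})

test_that("fully worn low-error participants are included", {
  x <- day_series(rep(10, 7 * 17280))
  v <- validate_wear(x, cal = 2)
  expect_true(v$included)
  expect_equal(v$exclusion_reason, "none")
  expect_equal(v$valid_days, 7L)
  expect_equal(v$covered_15min_slots, 96L)
})

test_that("fewer than 3 valid days excludes with the right reason", {
  # 4 days; days 3-4 almost entirely non-wear (wear 8 h < 16 h)
  n <- 4 * 17280
  flag <- rep("wear", n)
  for (d in 2:3) {
    idx <- d * 17280 + seq_len(16 * 720)  # 16 h of non-wear
    flag[idx] <- "nonwear"
  }
  v <- validate_wear(epoch_series("T", rep(10, n), flag))
  expect_equal(v$valid_days, 2L)
  expect_false(v$included)
  expect_equal(v$exclusion_reason, "few_valid_days")
})

test_that("post-calibration error above 10 mg excludes with reason calibration", {
  x <- day_series(rep(10, 7 * 17280))
  v <- validate_wear(x, cal = 12)
  expect_false(v$included)
  expect_equal(v$exclusion_reason, "calibration")
  # boundary: exactly 10 mg is still acceptable
  expect_true(validate_wear(x, cal = 10)$included)
})

test_that("a day needs strictly more than 16 h of wear to be valid", {
  n <- 4 * 17280
  flag <- rep("wear", n)
  # day 4: exactly 8 h non-wear -> exactly 16 h wear -> invalid
  flag[3 * 17280 + seq_len(8 * 720)] <- "nonwear"
  v <- validate_wear(epoch_series("T", rep(10, n), flag))
  expect_equal(v$valid_days, 3L)
  expect_true(v$included)
})

test_that("epoch CSV round-trips through disk", {
  gp <- generate_participant(activity_schedule(), days = 1, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_epoch_csv(gp$data, f)
  back <- read_epoch_csv(f, id = gp$data$id)
  expect_equal(back$enmo, gp$data$enmo, tolerance = 1e-12)
  expect_identical(back$flag, gp$data$flag)
  expect_equal(back$angle, gp$data$angle, tolerance = 1e-12)
  unlink(f)
})

test_that("raw CSV round-trips through disk", {
  sim <- simulate_still_recording(n_orientations = 3, dwell_sec = 5,
                                  seed = 2)
  f <- tempfile(fileext = ".csv")
  write_raw_csv(sim$rec, f)
  back <- read_raw_csv(f, id = "CAL")
  expect_equal(back$sample_rate, 20)
  expect_equal(back$data, sim$rec$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  unlink(f)
})
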