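# z-angle, sleep-window detection, sustained-inactivity labelling and
# sleep summaries.

test_that("z-angle hits the axis-aligned closed forms", {
  flat <- still_recording(c(0, 0, 1), secs = 10)
  expect_equal(z_angle(flat)$angle, c(90, 90))
  side <- still_recording(c(1, 0, 0), secs = 10)
  expect_equal(side$data[1, ], c(x = 1, y = 0, z = 0))
  expect_equal(z_angle(side)$angle, c(0, 0))
  down <- still_recording(c(0, 0, -1), secs = 10)
  expect_equal(z_angle(down)$angle, c(-90, -90))
})

test_that("z-angle equals the naive per-sample oracle", {
  set.seed(12)
  u <- matrix(rnorm(3 * 20 * 30), ncol = 3)
  u <- u + 0.5  # keep away from the zero-magnitude singularity
  rec <- triaxial_recording("T", u, 20)
  expect_equal(z_angle(rec)$angle, oracle_z_angle(u, 20),
               tolerance = 1e-6)
})

test_that("planted sleep windows are recovered within 15 minutes", {
  gp <- generate_participant(activity_schedule(), days = 3, seed = 5)
  w <- detect_sleep_window(gp$data)
  tr <- gp$truth$sleep_windows
  tr <- tr[tr$complete, ]
  expect_true(all(w$found))
  for (i in seq_len(nrow(w))) {
    t <- tr[tr$night == w$night[i], ]
    expect_lt(abs(w$onset_sec[i] - t$onset_sec) / 60, 15)
    expect_lt(abs(w$offset_sec[i] - t$offset_sec) / 60, 15)
  }
})

test_that("the longest merged rest block wins", {
  # angle series: jitter everywhere except a 6-h and a 2-h stable block
  # separated by 3 h, all within one noon-to-noon night
  set.seed(7)
  n <- 2 * 17280
  ang <- runif(n, -60, 60)
  stable <- function(from_h, len_h)
    (from_h * 720 + 1):((from_h + len_h) * 720)
  i6 <- stable(22, 6); i2 <- stable(31, 2)  # 22:00 + 6 h; 07:00(+1d) + 2 h
  ang[i6] <- 40 + rnorm(length(i6), 0, 0.5)
  ang[i2] <- 40 + rnorm(length(i2), 0, 0.5)
  x <- epoch_series("T", rep(10, n), angle = ang)
  w <- detect_sleep_window(x)
  expect_true(w$found[1])
  expect_equal(w$onset_sec[1], 22 * 3600, tolerance = 600)
  expect_equal(w$offset_sec[1], 28 * 3600, tolerance = 600)
})

test_that("a fully jittery night yields no window and is flagged", {
  set.seed(8)
  n <- 2 * 17280
  x <- epoch_series("T", rep(10, n), angle = runif(n, -60, 60))
  w <- detect_sleep_window(x)
  expect_false(any(w$found))
  expect_true(all(is.na(w$onset_sec)))
})

test_that("sustained inactivity is split at the window boundary", {
  set.seed(9)
  n <- 2 * 17280
  ang <- runif(n, -60, 60)
  # stable run 21:00-01:00; declared window covers only 23:00-06:00
  run <- (21 * 720 + 1):(25 * 720)
  ang[run] <- 30 + rnorm(length(run), 0, 0.4)
  x <- epoch_series("T", rep(10, n), angle = ang)
  win <- data.frame(night = 1, onset_sec = 23 * 3600,
                    offset_sec = 30 * 3600, found = TRUE)
  lab <- classify_sustained_inactivity(x, win)
  # inside the window -> sleep; same run before the window -> daytime
  expect_true(all(lab[(23 * 720 + 100):(25 * 720 - 60)] == "sleep"))
  expect_true(all(lab[(21 * 720 + 60):(23 * 720 - 60)] ==
                    "daytime_sustained_inactivity"))
  # an identical stable run at 14:00 is daytime sustained inactivity
  ang2 <- runif(n, -60, 60)
  run2 <- (14 * 720 + 1):(15 * 720)
  ang2[run2] <- 30 + rnorm(length(run2), 0, 0.4)
  x2 <- epoch_series("T", rep(10, n), angle = ang2)
  lab2 <- classify_sustained_inactivity(x2, win)
  expect_true(all(lab2[run2[60:660]] == "daytime_sustained_inactivity"))
})

test_that("sleep summaries follow the arithmetic of the examples", {
  n <- 3 * 17280
  # night 1: window 23:00-07:00 fully asleep
  x <- epoch_series("T", rep(0, n))
  w <- data.frame(night = 1, onset_sec = 23 * 3600,
                  offset_sec = 31 * 3600, found = TRUE)
  lab <- rep("sleep", n)
  s <- sleep_summary(w, lab, x)
  expect_equal(s$duration_min, 480)
  expect_equal(s$efficiency_pct, 100)
  expect_equal(s$midpoint_clock, "03:00")
  # 60 min of wake inside a 22:00-06:00 window
  w2 <- data.frame(night = 1, onset_sec = 22 * 3600,
                   offset_sec = 30 * 3600, found = TRUE)
  lab2 <- rep("sleep", n)
  lab2[(23 * 720 + 1):(24 * 720)] <- "other"
  s2 <- sleep_summary(w2, lab2, x)
  expect_equal(s2$duration_min, 420)
  expect_equal(s2$efficiency_pct, 87.5)
})

test_that("midpoint statistics are circular", {
  n <- 5 * 17280
  x <- epoch_series("T", rep(0, n))
  lab <- rep("sleep", n)
  # midpoints alternate 23:30 and 00:30 across 4 nights
  mk <- function(day, mid_h) {
    onset <- day * 86400 + mid_h * 3600 - 2 * 3600
    data.frame(onset_sec = onset, offset_sec = onset + 4 * 3600)
  }
  w <- rbind(mk(0, 23.5), mk(1, 24.5), mk(2, 23.5), mk(3, 24.5))
  w$night <- 1:4; w$found <- TRUE
  s <- sleep_summary(w, lab, x)
  expect_equal(s$midpoint_min, 0, tolerance = 1e-8)
  expect_equal(s$midpoint_sd_min, sqrt(1200), tolerance = 1e-6)
  # shifting every night by +1 h moves the midpoint, not its SD
  w1 <- w; w1$onset_sec <- w1$onset_sec + 3600
  w1$offset_sec <- w1$offset_sec + 3600
  s1 <- sleep_summary(w1, lab, x)
  expect_equal(s1$midpoint_min, 60, tolerance = 1e-8)
  expect_equal(s1$midpoint_sd_min, s$midpoint_sd_min, tolerance = 1e-10)
})

test_that("nightly sleep never exceeds the window duration", {
  for (seed in 1:5) {
    gp <- generate_participant(activity_schedule(), days = 3, seed = seed)
    w <- detect_sleep_window(gp$data)
    lab <- classify_sustained_inactivity(gp$data, w)
    s <- sleep_summary(w, lab, gp$data)
    expect_true(all(s$nights$sleep_min <= s$nights$window_min + 1e-9))
    expect_true(all(s$nights$efficiency >= 0 & s$nights$efficiency <= 100))
  }
})

test_that("ENMO-only input runs in surrogate mode and is marked approximate", {
  gp <- generate_participant(activity_schedule(), days = 2, seed = 14)
  x <- epoch_series(gp$data$id, gp$data$enmo, gp$data$flag)  # drop angles
  w <- detect_sleep_window(x)
  expect_true(attr(w, "approximate"))
  expect_true(any(w$found))
  tr <- gp$truth$sleep_windows[gp$truth$sleep_windows$complete, ]
  # surrogate mode is coarser; windows should still land near the night
  expect_lt(abs(w$onset_sec[1] - tr$onset_sec[1]) / 60, 60)
  expect_lt(abs(w$offset_sec[1] - tr$offset_sec[1]) / 60, 60)
})
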