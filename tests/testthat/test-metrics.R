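# Daily movement metrics: volume, intensity gradient, category times,
# bouts, MX metrics, hourly profile, aggregation.

no_sleep <- function(n = 17280) rep(FALSE, n)

test_that("average acceleration matches closed forms and the flat mean", {
  expect_equal(average_acceleration(rep(50, 17280)), 50)
  expect_equal(average_acceleration(c(rep(0, 8640), rep(40, 8640))), 20)
  x <- random_day(1)
  expect_equal(average_acceleration(x), sum(x) / length(x),
               tolerance = 1e-9)
})

test_that("two occupied bins reproduce the two-point slope exactly", {
  # t1 = 100 epochs in bin [0,25) (mid 12.5), t2 = 40 in [100,125) (mid 112.5)
  x <- c(rep(10, 100), rep(110, 40))
  ig <- intensity_gradient(x)
  expect_equal(ig$n_bins, 2L)
  t1 <- 100 * 5 / 60; t2 <- 40 * 5 / 60
  expect_equal(ig$gradient, (log(t2) - log(t1)) / (log(112.5) - log(12.5)))
  expect_equal(ig$r_squared, 1)
})

test_that("power-law days recover their construction exponent within 0.1", {
  for (e in c(-1.5, -2, -3)) {
    ig <- intensity_gradient(power_law_day(e))
    expect_true(ig$defined)
    expect_lt(abs(ig$gradient - e), 0.1)
  }
})

test_that("realistic synthetic days always have a negative gradient", {
  for (seed in 1:5) {
    gp <- generate_participant(activity_schedule(), days = 1, seed = seed)
    ig <- intensity_gradient(gp$data)
    expect_lt(ig$gradient, 0)
  }
})

test_that("fewer than two occupied bins is flagged, not a number", {
  ig <- intensity_gradient(rep(10, 17280))
  expect_false(ig$defined)
  expect_true(is.na(ig$gradient))
})

test_that("category times follow the threshold rules and the partition", {
  # 16 waking hours at 70 mg, 8 h sleep window at 0
  x <- c(rep(0, 8 * 720), rep(70, 16 * 720))
  sleep <- c(rep(TRUE, 8 * 720), rep(FALSE, 16 * 720))
  ct <- time_in_categories(x, sleep)
  expect_equal(ct$light, 960)
  expect_equal(ct$inactive_total, 0)
  expect_equal(ct$mvpa, 0)
  expect_equal(ct$sleep_window, 480)
  # boundary: alternating 200/0 averages to exactly 100 -> not MVPA
  x2 <- rep(c(200, 0), 17280 / 2)
  ct2 <- time_in_categories(x2, no_sleep())
  expect_equal(ct2$mvpa, 0)
  # epoch exactly at 40 mg counts as light, not inactive
  ct3 <- time_in_categories(rep(40, 17280), no_sleep())
  expect_equal(ct3$light, 1440)
  expect_equal(ct3$inactive_total, 0)
})

test_that("category times equal a per-epoch brute-force counter", {
  set.seed(11)
  # piecewise day with all three categories present
  x <- c(rep(20, 6000), rep(70, 5000), rep(150, 2280), rep(5, 4000))
  x <- x[sample.int(length(x))]
  sleep <- c(rep(TRUE, 5000), rep(FALSE, 12280))
  ct <- time_in_categories(x, sleep)
  mm <- colMeans(matrix(x, nrow = 12))
  wake_min <- colSums(matrix(sleep, nrow = 12)) == 0
  mvpa_min <- wake_min & mm > 100
  in_mvpa <- rep(mvpa_min, each = 12)
  expect_equal(ct$mvpa, sum(mvpa_min))
  expect_equal(ct$inactive_total,
               sum(!sleep & !in_mvpa & x < 40) * 5 / 60)
  expect_equal(ct$light, sum(!sleep & !in_mvpa & x >= 40) * 5 / 60)
  expect_equal(ct$inactive_total + ct$light + ct$mvpa + ct$sleep_window,
               1440, tolerance = 1e-9)
})

test_that("inactivity bouts require strictly more than 30 consecutive minutes", {
  base <- rep(100, 17280)
  x <- base; x[1:(45 * 12)] <- 10
  expect_equal(inactivity_bouts(x, no_sleep()), 45)
  x <- base; x[1:(25 * 12)] <- 10
  expect_equal(inactivity_bouts(x, no_sleep()), 0)
  # a single interrupting epoch splits a 50-min run into two short runs
  x <- base; x[1:(50 * 12)] <- 10; x[20 * 12] <- 120
  expect_equal(inactivity_bouts(x, no_sleep()), 0)
  # exactly 30 min does not count ("> 30 min" strict)
  x <- base; x[1:(30 * 12)] <- 10
  expect_equal(inactivity_bouts(x, no_sleep()), 0)
})

test_that("accumulated MX equals the full-sort oracle", {
  expect_equal(mx_accumulated(rep(50, 17280), 5), 50)
  x <- c(rep(200, 60), rep(10, 17220))
  expect_equal(mx_accumulated(x, 5), 200)
  expect_equal(mx_accumulated(x, 10), 10)
  y <- random_day(3)
  for (d in c(5, 10, 30, 60, 120))
    expect_identical(mx_accumulated(y, d), oracle_mx_acc(y, d))
  expect_error(mx_accumulated(y[1:100], 120), "exceeds")
})

test_that("continuous MX equals the exhaustive-window oracle", {
  expect_equal(mx_continuous(rep(50, 17280), 5), 50)
  x <- rep(10, 2880); x[1001:1060] <- 150  # 5-min block at 150
  expect_equal(mx_continuous(x, 5), 150)
  expect_equal(mx_continuous(x, 10), 10)
  y <- random_day(4, n = 2880)
  for (d in c(1, 2, 5, 10))
    expect_identical(mx_continuous(y, d), oracle_mx_cont(y, d))
})

test_that("the alternative best-window-quantile method matches its oracle", {
  thr <- intensity_thresholds(mx_cont_method = "best_window_quantile")
  y <- random_day(5, n = 2880)
  n <- 60; k <- ceiling(0.25 * n)
  means <- vapply(seq_len(length(y) - n + 1),
                  function(i) mean(y[i:(i + n - 1)]), 0)
  i <- which.max(means)
  expect_equal(mx_continuous(y, 5, thr = thr), sort(y[i:(i + n - 1)])[k])
  # and it can only be <= the default max-over-windows form
  expect_lte(mx_continuous(y, 5, thr = thr), mx_continuous(y, 5))
})

test_that("MX profiles are monotone in duration and acc dominates cont", {
  for (seed in 1:25) {
    y <- random_day(100 + seed)
    p <- mx_profile(y)
    expect_true(all(diff(p$acc) <= 0))
    expect_true(all(diff(p$cont) <= 0))
    expect_true(all(p$acc >= p$cont))
  }
})

test_that("hourly profile averages each clock hour", {
  expect_equal(hourly_profile(rep(30, 17280)), rep(30, 24))
  x <- rep(0, 17280); x[(10 * 720 + 1):(11 * 720)] <- 120
  hp <- hourly_profile(x)
  expect_equal(hp[11], 120)
  expect_equal(sum(hp), 120)
  y <- random_day(6)
  oracle <- vapply(1:24, function(h) mean(y[((h - 1) * 720 + 1):(h * 720)]), 0)
  expect_equal(hourly_profile(y), oracle, tolerance = 1e-12)
})

test_that("aggregation averages metrics across days", {
  mk <- function(v) daily_profile(rep(v, 17280), no_sleep(), day = 1)
  p1 <- mk(10); p2 <- mk(20); p3 <- mk(30)
  agg <- aggregate_days(list(p1, p2, p3))
  expect_equal(agg$average_acceleration, 20)
  expect_equal(agg$mx$acc, (p1$mx$acc + p2$mx$acc + p3$mx$acc) / 3)
  # idempotence on identical days
  agg1 <- aggregate_days(list(p2, p2))
  expect_equal(agg1$average_acceleration, p2$average_acceleration)
  expect_equal(agg1$mx, p2$mx)
  expect_error(aggregate_days(list()), "no valid days")
})
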