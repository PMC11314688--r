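# 24-h movement-profile metrics computed per calendar day from 5-s ENMO
# epochs, and their across-day aggregation.

#' Intensity thresholds and metric settings
#'
#' @param inactive_below mg; epochs strictly below are inactive (default 40).
#' @param mvpa_above mg; 1-min means strictly above are MVPA (default 100).
#' @param epoch_length s.
#' @param mvpa_interval_min re-epoching interval for MVPA, minutes.
#' @param bout_min minutes; inactive runs strictly longer count as bouts.
#' @param ig_bin_width,ig_max_mg intensity-gradient binning (25-mg bins,
#'   0-4000 mg).
#' @param mx_durations minutes for the MX metrics.
#' @param mx_cont_method `"max_window_quantile"` (default: maximum over all
#'   windows of the within-window lower quartile) or
#'   `"best_window_quantile"` (lower quartile of the window with maximal
#'   mean).
#' @param mx_cont_quantile within-window quantile for the continuous MX
#'   metric (default 0.25: 75% of the window lies at or above the value).
#' @return a list of class `intensity_thresholds`.
#' @export
intensity_thresholds <- function(inactive_below = 40, mvpa_above = 100,
                                 epoch_length = EPOCH_LENGTH_DEFAULT,
                                 mvpa_interval_min = 1, bout_min = 30,
                                 ig_bin_width = 25, ig_max_mg = 4000,
                                 mx_durations = c(5, 10, 30, 60, 120),
                                 mx_cont_method = c("max_window_quantile",
                                                    "best_window_quantile"),
                                 mx_cont_quantile = 0.25) {
  if (!(inactive_below > 0 && inactive_below < mvpa_above))
    stop("need 0 < inactive_below < mvpa_above")
  structure(list(inactive_below = inactive_below, mvpa_above = mvpa_above,
                 epoch_length = epoch_length,
                 mvpa_interval_min = mvpa_interval_min, bout_min = bout_min,
                 ig_bin_width = ig_bin_width, ig_max_mg = ig_max_mg,
                 mx_durations = mx_durations,
                 mx_cont_method = match.arg(mx_cont_method),
                 mx_cont_quantile = mx_cont_quantile),
            class = "intensity_thresholds")
}

.enmo_vec <- function(x) {
  if (inherits(x, "epoch_series")) x$enmo else as.numeric(x)
}

# logical per-epoch in-sleep-window mask from a window table (start_sec /
# end_sec, absolute seconds), or pass a logical vector through
.sleep_mask <- function(epochs, sleep) {
  if (is.logical(sleep)) return(sleep)
  n <- length(.enmo_vec(epochs))
  mask <- rep(FALSE, n)
  if (is.null(sleep) || !nrow(sleep)) return(mask)
  nm <- if (all(c("onset_sec", "offset_sec") %in% names(sleep)))
    c("onset_sec", "offset_sec") else c("start_sec", "end_sec")
  el <- if (inherits(epochs, "epoch_series")) epochs$epoch_length else
    EPOCH_LENGTH_DEFAULT
  s0 <- if (inherits(epochs, "epoch_series")) epochs$start_sec else 0
  t0 <- s0 + (seq_len(n) - 1) * el
  for (i in seq_len(nrow(sleep)))
    mask[t0 >= sleep[[nm[1]]][i] & t0 < sleep[[nm[2]]][i]] <- TRUE
  mask
}

.check_complete <- function(epochs) {
  if (inherits(epochs, "epoch_series") && any(epochs$flag == "nonwear"))
    stop("series still contains unimputed non-wear epochs")
  invisible(TRUE)
}

#' Average acceleration over the 24-h day
#'
#' Arithmetic mean of all epoch ENMO values: the volume proxy of the
#' 24-h movement profile, in mg.
#'
#' @param epochs one day of epochs ([epoch_series()] or numeric mg vector).
#' @return mean ENMO, mg.
#' @export
average_acceleration <- function(epochs) {
  .check_complete(epochs)
  mean(.enmo_vec(epochs))
}

#' Intensity gradient of one day
#'
#' Time (minutes) accumulated in 25-mg intensity bins spanning 0-4000 mg is
#' regressed, on the natural-log/natural-log scale, against the bin
#' mid-intensity over occupied bins; the OLS slope is the gradient. It is
#' negative whenever accumulated time falls away with increasing intensity.
#'
#' @param epochs one day of epochs.
#' @param thr an [intensity_thresholds()].
#' @return list of class `intensity_gradient`: `gradient`, `intercept`,
#'   `r_squared`, `n_bins`, `defined`.
#' @export
intensity_gradient <- function(epochs, thr = intensity_thresholds()) {
  x <- .enmo_vec(epochs)
  el <- thr$epoch_length
  breaks <- seq(0, thr$ig_max_mg, by = thr$ig_bin_width)
  x <- x[x < thr$ig_max_mg]
  cnt <- tabulate(findInterval(x, breaks), nbins = length(breaks) - 1L)
  mid <- breaks[-length(breaks)] + thr$ig_bin_width / 2
  t_min <- cnt * el / 60
  keep <- t_min > 0
  if (sum(keep) < 2L)
    return(structure(list(gradient = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n_bins = sum(keep),
                          defined = FALSE), class = "intensity_gradient"))
  fit <- lm(log(t_min[keep]) ~ log(mid[keep]))
  structure(list(gradient = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_bins = as.integer(sum(keep)), defined = TRUE),
            class = "intensity_gradient")
}

#' Waking time in intensity categories
#'
#' MVPA is counted on 1-min re-epoched means (a fully waking minute whose
#' mean ENMO strictly exceeds `mvpa_above`); the remaining waking 5-s
#' epochs are split at `inactive_below` into inactive (strictly below) and
#' light, so that inactive + light + MVPA + sleep-window time partitions
#' the 24-h day.
#'
#' @param epochs one day of epochs.
#' @param sleep per-epoch logical in-window mask or a window table
#'   (`start_sec`/`end_sec`); `NULL` computes over the full day with a
#'   warning.
#' @param thr an [intensity_thresholds()].
#' @return list: `inactive_total`, `light`, `mvpa`, `sleep_window`
#'   (minutes).
#' @export
time_in_categories <- function(epochs, sleep, thr = intensity_thresholds()) {
  x <- .enmo_vec(epochs)
  if (is.null(sleep)) {
    warning("no sleep window supplied; categorising the full day as waking")
    sleep <- rep(FALSE, length(x))
  }
  asleep <- .sleep_mask(epochs, sleep)
  el <- thr$epoch_length
  epm <- as.integer(thr$mvpa_interval_min * 60 / el)
  if (length(x) %% epm != 0)
    stop("day length is not a whole number of MVPA intervals")
  mm <- colMeans(matrix(x, nrow = epm))
  waking_min <- colSums(matrix(asleep, nrow = epm)) == 0L
  mvpa_min <- waking_min & mm > thr$mvpa_above
  in_mvpa <- rep(mvpa_min, each = epm)
  inact <- !asleep & !in_mvpa & x < thr$inactive_below
  light <- !asleep & !in_mvpa & x >= thr$inactive_below
  list(inactive_total = sum(inact) * el / 60,
       light = sum(light) * el / 60,
       mvpa = sum(mvpa_min) * thr$mvpa_interval_min,
       sleep_window = sum(asleep) * el / 60)
}

#' Minutes accumulated in prolonged inactivity bouts
#'
#' Maximal runs of consecutive waking epochs strictly below the inactivity
#' threshold; runs strictly longer than `bout_min` minutes contribute their
#' full duration. Runs are broken by any epoch at or above the threshold
#' and by the sleep window.
#'
#' @inheritParams time_in_categories
#' @return minutes in bouts.
#' @export
inactivity_bouts <- function(epochs, sleep, thr = intensity_thresholds()) {
  x <- .enmo_vec(epochs)
  asleep <- .sleep_mask(epochs, if (is.null(sleep))
    rep(FALSE, length(x)) else sleep)
  cond <- !asleep & x < thr$inactive_below
  r <- rle(cond)
  len_min <- r$lengths[r$values] * thr$epoch_length / 60
  sum(len_min[len_min > thr$bout_min])
}

#' MX metric, accumulated variant
#'
#' The acceleration above (or at) which the participant's most active X
#' minutes of the day are accumulated: the (X-in-epochs)-th largest epoch
#' value of the day.
#'
#' @param epochs one day of epochs.
#' @param duration_min X, minutes.
#' @param epoch_length s.
#' @return mg.
#' @export
mx_accumulated <- function(epochs, duration_min,
                           epoch_length = EPOCH_LENGTH_DEFAULT) {
  x <- .enmo_vec(epochs)
  n_ep <- as.integer(duration_min * 60 / epoch_length)
  if ((duration_min * 60) %% epoch_length != 0)
    stop("duration must be a whole number of epochs")
  if (n_ep > length(x)) stop("duration exceeds the day length")
  sort(x, decreasing = TRUE)[n_ep]
}

#' MX metric, continuous variant
#'
#' The largest acceleration `a` such that some contiguous X-min window of
#' the day spends at least 75% of its time at or above `a`: the maximum
#' over all windows (stride one epoch, not wrapping midnight) of the
#' within-window lower empirical quartile (order statistic at
#' `ceiling(0.25 n)`, no interpolation). The alternative
#' `"best_window_quantile"` method instead reports the lower quartile of
#' the single window with maximal mean.
#'
#' @inheritParams mx_accumulated
#' @param thr an [intensity_thresholds()] (method, quantile).
#' @return mg.
#' @export
mx_continuous <- function(epochs, duration_min,
                          epoch_length = EPOCH_LENGTH_DEFAULT,
                          thr = intensity_thresholds()) {
  x <- .enmo_vec(epochs)
  n_ep <- as.integer(duration_min * 60 / epoch_length)
  if ((duration_min * 60) %% epoch_length != 0)
    stop("duration must be a whole number of epochs")
  if (n_ep > length(x)) stop("duration exceeds the day length")
  k <- as.integer(ceiling(thr$mx_cont_quantile * n_ep))
  if (thr$mx_cont_method == "max_window_quantile") {
    max(.roll_kth_smallest(x, n_ep, k))
  } else {
    i <- which.max(.roll_mean(x, n_ep))
    sort(x[i:(i + n_ep - 1L)])[k]
  }
}

#' Full MX profile of one day
#' @inheritParams mx_continuous
#' @return data frame: `duration` (min), `acc` (mg), `cont` (mg).
#' @export
mx_profile <- function(epochs, thr = intensity_thresholds(),
                       epoch_length = thr$epoch_length) {
  data.frame(
    duration = thr$mx_durations,
    acc = vapply(thr$mx_durations, function(d)
      mx_accumulated(epochs, d, epoch_length), 0),
    cont = vapply(thr$mx_durations, function(d)
      mx_continuous(epochs, d, epoch_length, thr), 0))
}

#' Hour-by-hour mean acceleration
#' @param epochs one full day of epochs.
#' @return numeric vector of 24 hourly mean ENMO values, mg.
#' @export
hourly_profile <- function(epochs) {
  x <- .enmo_vec(epochs)
  if (length(x) %% 24 != 0) stop("day length is not a whole number of hours")
  colMeans(matrix(x, nrow = length(x) / 24))
}

#' All movement metrics for one calendar day
#'
#' @param epochs one complete day of imputed epochs.
#' @param sleep sleep-window mask or table for the day (see
#'   [time_in_categories()]).
#' @param thr an [intensity_thresholds()].
#' @param day day index carried through to the output.
#' @return list of class `daily_profile`.
#' @export
daily_profile <- function(epochs, sleep, thr = intensity_thresholds(),
                          day = NA_integer_) {
  .check_complete(epochs)
  cats <- time_in_categories(epochs, sleep, thr)
  structure(list(
    day = day,
    average_acceleration = average_acceleration(epochs),
    ig = intensity_gradient(epochs, thr),
    inactive_total = cats$inactive_total,
    inactive_bouted = inactivity_bouts(epochs, sleep, thr),
    light = cats$light, mvpa = cats$mvpa,
    sleep_window = cats$sleep_window,
    mx = mx_profile(epochs, thr),
    hourly = hourly_profile(epochs)), class = "daily_profile")
}

#' Average daily profiles across valid days
#'
#' Unweighted mean of every metric across the supplied days (MX metrics
#' averaged per duration, hourly means per hour).
#'
#' @param profiles list of `daily_profile` objects (the participant's
#'   valid days).
#' @return list of class `participant_profile` with the same fields.
#' @export
aggregate_days <- function(profiles) {
  if (!length(profiles)) stop("no valid days to aggregate")
  m <- function(f) mean(vapply(profiles, function(p) p[[f]], 0))
  igs <- vapply(profiles, function(p) p$ig$gradient, 0)
  mx <- Reduce(`+`, lapply(profiles, function(p)
    as.matrix(p$mx[, c("acc", "cont")]))) / length(profiles)
  structure(list(
    n_days = length(profiles),
    average_acceleration = m("average_acceleration"),
    ig_gradient = mean(igs[is.finite(igs)]),
    inactive_total = m("inactive_total"),
    inactive_bouted = m("inactive_bouted"),
    light = m("light"), mvpa = m("mvpa"),
    sleep_window = m("sleep_window"),
    mx = data.frame(duration = profiles[[1]]$mx$duration,
                    acc = mx[, "acc"], cont = mx[, "cont"]),
    hourly = Reduce(`+`, lapply(profiles, `[[`, "hourly")) /
      length(profiles)), class = "participant_profile")
}

#' Flatten a participant profile to one metric-table row
#' @param p a `participant_profile`.
#' @return one-row data frame with named metric columns (`M5_ACC`, ...).
#' @export
profile_row <- function(p) {
  mx <- setNames(
    c(p$mx$acc, p$mx$cont),
    c(sprintf("M%d_ACC", p$mx$duration), sprintf("M%d_CONT", p$mx$duration)))
  cbind(data.frame(avg_acceleration = p$average_acceleration,
                   intensity_gradient = p$ig_gradient,
                   inactive_total = p$inactive_total,
                   inactive_bouted = p$inactive_bouted,
                   light = p$light, mvpa = p$mvpa,
                   valid_days = p$n_days),
        as.data.frame(as.list(mx)))
}
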