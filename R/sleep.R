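# Sleep-period-window detection from the wrist z-angle (heuristic of the
# distribution-of-change type: low variation in arm angle sustained over
# tens of minutes marks the night-time rest window), classification of
# sustained inactivity, and sleep summary statistics.

.z_angle_samples <- function(d) {
  hyp <- sqrt(d[, 1]^2 + d[, 2]^2)
  ang <- atan(d[, 3] / hyp) * 180 / pi
  ang[hyp == 0 & d[, 3] == 0] <- NA_real_
  ang[hyp == 0 & d[, 3] > 0] <- 90
  ang[hyp == 0 & d[, 3] < 0] <- -90
  ang
}

#' Per-epoch wrist z-angle
#'
#' The angle of the acceleration vector relative to the horizontal plane,
#' `atan(z / sqrt(x^2 + y^2)) * 180 / pi`, averaged per 5-s epoch.
#' Zero-magnitude samples yield an undefined (NA) contribution.
#'
#' @param rec a calibrated [triaxial_recording()].
#' @param epoch_length epoch length, seconds.
#' @return list of class `z_angle_series`: `angle` (degrees, one value per
#'   epoch), `epoch_length`, `start_sec`.
#' @export
z_angle <- function(rec, epoch_length = EPOCH_LENGTH_DEFAULT) {
  stopifnot(inherits(rec, "triaxial_recording"))
  spe <- rec$sample_rate * epoch_length
  if (spe %% 1 != 0)
    stop("sample_rate x epoch_length must be an integer number of samples")
  spe <- as.integer(spe)
  ne <- nrow(rec$data) %/% spe
  a <- .z_angle_samples(rec$data[seq_len(ne * spe), , drop = FALSE])
  structure(list(angle = colMeans(matrix(a, nrow = spe)),
                 epoch_length = epoch_length, start_sec = rec$start_sec),
            class = "z_angle_series")
}

# Coerce supported inputs to an angle series. Epoch series generated in
# this package carry the angle; ENMO-only input falls back to a surrogate
# where the ENMO value itself plays the role of the changing signal.
.angle_input <- function(x) {
  if (inherits(x, "z_angle_series"))
    return(list(sig = x$angle, el = x$epoch_length, s0 = x$start_sec,
                surrogate = FALSE))
  if (inherits(x, "epoch_series")) {
    if (!is.null(x$angle))
      return(list(sig = x$angle, el = x$epoch_length, s0 = x$start_sec,
                  surrogate = FALSE))
    return(list(sig = x$enmo, el = x$epoch_length, s0 = x$start_sec,
                surrogate = TRUE))
  }
  stop("expected a z_angle_series or epoch_series")
}

.roll_median <- function(x, k) {
  if (k %% 2 == 0) k <- k + 1L
  as.numeric(runmed(x, k, endrule = "median"))
}

#' Detect the nightly sleep period window
#'
#' For each noon-to-noon night: 5-min rolling medians of the absolute
#' successive z-angle differences are thresholded at 15 times their 10th
#' percentile (capped within `cap_band`); runs below threshold lasting at
#' least `min_block_min` minutes are candidate rest blocks; candidates
#' separated by gaps shorter than `max_gap_min` are merged; the longest
#' merged block is the night's sleep window. With ENMO-only input the same
#' machinery runs on the ENMO series (surrogate mode, `approximate = TRUE`,
#' cap band in mg).
#'
#' @param x a `z_angle_series` or [epoch_series()].
#' @param hdcza parameter list: `multiplier` (15), `percentile` (0.10),
#'   `cap_band` (degrees, default c(0.1, 5)), `roll_min` (5),
#'   `min_block_min` (30), `max_gap_min` (60),
#'   `cap_band_surrogate` (mg, default c(1, 10)).
#' @return data frame of class `sleep_windows`: one row per night with
#'   `night`, `onset_sec`, `offset_sec` (absolute seconds) and `found`;
#'   nights without any qualifying block have `found = FALSE` and NA times.
#'   Attribute `approximate` marks surrogate mode.
#' @export
detect_sleep_window <- function(x, hdcza = hdcza_params()) {
  inp <- .angle_input(x)
  n <- length(inp$sig)
  el <- inp$el
  d <- c(0, abs(diff(inp$sig)))
  if (inp$surrogate) d <- inp$sig
  rm5 <- .roll_median(d, as.integer(hdcza$roll_min * 60 / el))
  t0 <- inp$s0 + (seq_len(n) - 1) * el
  # noon-to-noon nights covered by the series
  first_noon <- (t0[1] %/% 86400) * 86400 + 43200
  if (first_noon < t0[1]) first_noon <- first_noon + 86400
  nights <- list()
  night_id <- 0L
  ns <- first_noon
  band <- if (inp$surrogate) hdcza$cap_band_surrogate else hdcza$cap_band
  while (ns + 86400 <= t0[n] + el) {
    night_id <- night_id + 1L
    sel <- which(t0 >= ns & t0 < ns + 86400)
    v <- rm5[sel]
    thr <- hdcza$multiplier * quantile(v, hdcza$percentile, names = FALSE)
    thr <- min(max(thr, band[1]), band[2])
    below <- v < thr
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    min_len <- hdcza$min_block_min * 60 / el
    cand <- r$values & r$lengths >= min_len
    row <- data.frame(night = night_id, onset_sec = NA_real_,
                      offset_sec = NA_real_, found = FALSE)
    if (any(cand)) {
      cs <- starts[cand]; ce <- ends[cand]
      # merge candidates separated by gaps < max_gap_min
      merged_s <- cs[1]; merged_e <- ce[1]
      out_s <- c(); out_e <- c()
      if (length(cs) > 1) for (i in 2:length(cs)) {
        if ((cs[i] - merged_e - 1L) * el < hdcza$max_gap_min * 60) {
          merged_e <- ce[i]
        } else {
          out_s <- c(out_s, merged_s); out_e <- c(out_e, merged_e)
          merged_s <- cs[i]; merged_e <- ce[i]
        }
      }
      out_s <- c(out_s, merged_s); out_e <- c(out_e, merged_e)
      best <- which.max(out_e - out_s)
      row$onset_sec <- t0[sel[out_s[best]]]
      row$offset_sec <- t0[sel[out_e[best]]] + el
      row$found <- TRUE
    }
    nights[[night_id]] <- row
    ns <- ns + 86400
  }
  res <- if (length(nights)) do.call(rbind, nights) else
    data.frame(night = integer(), onset_sec = numeric(),
               offset_sec = numeric(), found = logical())
  class(res) <- c("sleep_windows", "data.frame")
  attr(res, "approximate") <- inp$surrogate
  res
}

#' HDCZA-style detection parameters
#' @param multiplier threshold multiplier on the angle-change percentile.
#' @param percentile percentile of the rolling-median series.
#' @param cap_band allowed threshold range, degrees.
#' @param roll_min rolling-median window, minutes.
#' @param min_block_min minimum candidate rest block, minutes.
#' @param max_gap_min candidate gaps shorter than this merge, minutes.
#' @param sustained_min minimum sustained-inactivity run, minutes.
#' @param cap_band_surrogate allowed threshold range in surrogate (ENMO)
#'   mode, mg.
#' @return named list.
#' @export
hdcza_params <- function(multiplier = 15, percentile = 0.10,
                         cap_band = c(0.1, 5), roll_min = 5,
                         min_block_min = 30, max_gap_min = 60,
                         sustained_min = 5,
                         cap_band_surrogate = c(1, 10)) {
  list(multiplier = multiplier, percentile = percentile,
       cap_band = cap_band, roll_min = roll_min,
       min_block_min = min_block_min, max_gap_min = max_gap_min,
       sustained_min = sustained_min,
       cap_band_surrogate = cap_band_surrogate)
}

#' Label sustained inactivity as sleep or daytime sustained inactivity
#'
#' Sustained-inactivity runs (rolling-median angle change below the
#' detection threshold for at least `sustained_min` minutes) are labelled
#' `"sleep"` inside a sleep window and `"daytime_sustained_inactivity"`
#' outside; runs straddling a window edge are split at the boundary. All
#' other epochs are `"other"`.
#'
#' @param x a `z_angle_series` or [epoch_series()].
#' @param windows a `sleep_windows` table from [detect_sleep_window()].
#' @param hdcza see [hdcza_params()].
#' @return character vector, one label per epoch.
#' @export
classify_sustained_inactivity <- function(x, windows,
                                          hdcza = hdcza_params()) {
  inp <- .angle_input(x)
  n <- length(inp$sig)
  el <- inp$el
  d <- c(0, abs(diff(inp$sig)))
  if (inp$surrogate) d <- inp$sig
  rm5 <- .roll_median(d, as.integer(hdcza$roll_min * 60 / el))
  band <- if (inp$surrogate) hdcza$cap_band_surrogate else hdcza$cap_band
  thr <- hdcza$multiplier * quantile(rm5, hdcza$percentile, names = FALSE)
  thr <- min(max(thr, band[1]), band[2])
  below <- rm5 < thr
  r <- rle(below)
  sustained <- rep(r$values & r$lengths >= hdcza$sustained_min * 60 / el,
                   r$lengths)
  t0 <- inp$s0 + (seq_len(n) - 1) * el
  in_win <- rep(FALSE, n)
  w <- windows[windows$found, , drop = FALSE]
  for (i in seq_len(nrow(w)))
    in_win[t0 >= w$onset_sec[i] & t0 < w$offset_sec[i]] <- TRUE
  out <- rep("other", n)
  out[sustained & in_win] <- "sleep"
  out[sustained & !in_win] <- "daytime_sustained_inactivity"
  out
}

.circular_midpoint_stats <- function(mid_min) {
  th <- mid_min / MIN_PER_DAY * 2 * pi
  m <- atan2(mean(sin(th)), mean(cos(th)))
  centre <- (m / (2 * pi) * MIN_PER_DAY) %% MIN_PER_DAY
  if (MIN_PER_DAY - centre < 1e-6) centre <- 0
  dev <- ((mid_min - centre + 720) %% MIN_PER_DAY) - 720
  list(mean_min = centre, sd_min = if (length(dev) > 1) sd(dev) else 0)
}

#' Per-participant sleep summary
#'
#' Per night: sleep duration = minutes labelled sleep inside the window;
#' efficiency = 100 x duration / window length. Across nights: unweighted
#' means, plus the circular mean of nightly window midpoints and the
#' standard deviation of midpoints after unwrapping about that mean.
#'
#' @param windows a `sleep_windows` table.
#' @param labels per-epoch labels from [classify_sustained_inactivity()].
#' @param x the series the labels refer to (for the epoch grid).
#' @return list of class `sleep_summary`: `n_nights`, `duration_min`,
#'   `efficiency_pct`, `midpoint_min` (minutes after midnight),
#'   `midpoint_clock`, `midpoint_sd_min`, and the per-night table.
#' @export
sleep_summary <- function(windows, labels, x) {
  inp <- .angle_input(x)
  w <- windows[windows$found, , drop = FALSE]
  if (nrow(w) < 1L) stop("no nights with a detected sleep window")
  t0 <- inp$s0 + (seq_along(inp$sig) - 1) * inp$el
  per <- do.call(rbind, lapply(seq_len(nrow(w)), function(i) {
    sel <- t0 >= w$onset_sec[i] & t0 < w$offset_sec[i]
    dur_win <- (w$offset_sec[i] - w$onset_sec[i]) / 60
    slp <- sum(labels[sel] == "sleep") * inp$el / 60
    data.frame(night = w$night[i], window_min = dur_win, sleep_min = slp,
               efficiency = 100 * slp / dur_win,
               midpoint_min = (((w$onset_sec[i] + w$offset_sec[i]) / 2) /
                                 60) %% MIN_PER_DAY)
  }))
  circ <- .circular_midpoint_stats(per$midpoint_min)
  structure(list(
    n_nights = nrow(per),
    duration_min = mean(per$sleep_min),
    efficiency_pct = mean(per$efficiency),
    midpoint_min = circ$mean_min,
    midpoint_clock = .fmt_clock(as.integer(round(circ$mean_min))),
    midpoint_sd_min = circ$sd_min,
    nights = per), class = "sleep_summary")
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat(sprintf(
    "<sleep_summary> %d nights: %.0f min/night, efficiency %.1f%%, midpoint %s (SD %.1f min)\n",
    x$n_nights, x$duration_min, x$efficiency_pct, x$midpoint_clock,
    x$midpoint_sd_min))
  invisible(x)
}
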