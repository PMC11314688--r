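# Daily activity schedules for the synthetic cohort generator.

.clock_min <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  p <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(p, function(h) as.integer(h[1]) * 60L + as.integer(h[2]), 1L)
}

.fmt_clock <- function(m) sprintf("%02d:%02d", (m %/% 60) %% 24, m %% 60)

#' Daily activity schedule for one synthetic participant
#'
#' Describes one 24-h day as a sleep window, planted activity bouts, planted
#' non-wear gaps, and filler wake activity drawn from a set of intensity
#' levels. The same schedule is repeated (with fresh noise and filler order)
#' on every simulated day.
#'
#' @param sleep_onset clock time (`"HH:MM"` or minutes from midnight) at
#'   which the nightly sleep window opens.
#' @param sleep_duration sleep-window duration in minutes.
#' @param sleep_efficiency fraction of the window generated as sleep-like
#'   signal; the remainder becomes brief wakeful arousals inside the window.
#' @param wake_intensity_levels data frame with columns `intensity` (mg) and
#'   `minutes` (target minutes/day); filler wake time is allocated to levels
#'   proportionally to `minutes`.
#' @param bout_plan data frame with columns `start` (clock time), `duration`
#'   (minutes) and `intensity` (mg): activity bouts planted at fixed times.
#' @param nonwear_segments data frame with columns `start` (clock time) and
#'   `duration` (minutes): planted zero-signal non-wear gaps.
#' @param noise_sd per-epoch Gaussian noise on wake intensities, mg
#'   (truncated so ENMO stays non-negative).
#' @param sleep_enmo_mean,sleep_enmo_sd mg; per-epoch ENMO during sleep.
#' @param arousal_intensity mg; wake-level intensity of in-window arousals.
#' @param sleep_angle_jitter_sd degrees; per-epoch z-angle jitter in sleep.
#' @param inactive_block_min,active_block_min minutes; filler block lengths
#'   for levels below/above the 40 mg inactivity threshold (long inactive
#'   blocks create the prolonged sedentary bouts typical of this cohort).
#' @return An object of class `activity_schedule`.
#' @export
activity_schedule <- function(sleep_onset = "23:00",
                              sleep_duration = 465,
                              sleep_efficiency = 0.86,
                              wake_intensity_levels = data.frame(
                                intensity = c(15, 72),
                                minutes = c(770, 185)),
                              bout_plan = data.frame(
                                start = c("10:30", "17:00"),
                                duration = c(10, 10),
                                intensity = c(140, 250)),
                              nonwear_segments = NULL,
                              noise_sd = 5,
                              sleep_enmo_mean = 2, sleep_enmo_sd = 1.5,
                              arousal_intensity = 30,
                              sleep_angle_jitter_sd = 1,
                              inactive_block_min = 40,
                              active_block_min = 15) {
  if (sleep_duration <= 0 || sleep_duration > MIN_PER_DAY)
    stop("sleep_duration must be in (0, 1440] minutes")
  if (sleep_efficiency < 0 || sleep_efficiency > 1)
    stop("sleep_efficiency must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  lv <- wake_intensity_levels
  if (is.null(lv) || nrow(lv) == 0L)
    lv <- data.frame(intensity = 0, minutes = 1)
  if (any(lv$intensity < 0) || any(lv$minutes <= 0))
    stop("wake intensity levels need intensity >= 0 mg and minutes > 0")
  bouts <- bout_plan
  if (!is.null(bouts) && nrow(bouts)) {
    if (any(bouts$intensity < 0) || any(bouts$duration <= 0))
      stop("bouts need intensity >= 0 mg and duration > 0 min")
    bouts$start <- .clock_min(bouts$start)
  } else bouts <- data.frame(start = integer(), duration = numeric(),
                             intensity = numeric())
  nw <- nonwear_segments
  if (!is.null(nw) && nrow(nw)) {
    if (any(nw$duration <= 0)) stop("non-wear segments need duration > 0")
    nw$start <- .clock_min(nw$start)
  } else nw <- data.frame(start = integer(), duration = numeric())

  sched <- structure(
    list(sleep_onset = .clock_min(sleep_onset),
         sleep_duration = as.integer(sleep_duration),
         sleep_efficiency = sleep_efficiency,
         wake_intensity_levels = lv, bout_plan = bouts,
         nonwear_segments = nw, noise_sd = noise_sd,
         sleep_enmo_mean = sleep_enmo_mean, sleep_enmo_sd = sleep_enmo_sd,
         arousal_intensity = arousal_intensity,
         sleep_angle_jitter_sd = sleep_angle_jitter_sd,
         inactive_block_min = as.integer(inactive_block_min),
         active_block_min = as.integer(active_block_min)),
    class = "activity_schedule")
  .check_schedule_overlap(sched)
  sched
}

# Minute-level occupancy of one 24-h day; errors name the overlapping pair.
.check_schedule_overlap <- function(s) {
  owner <- rep(NA_character_, MIN_PER_DAY)
  claim <- function(start, dur, label) {
    mins <- (start + seq_len(dur) - 1L) %% MIN_PER_DAY
    hit <- !is.na(owner[mins + 1L])
    if (any(hit)) {
      at <- mins[which(hit)[1]]
      stop(sprintf("schedule overlap: %s overlaps %s at %s",
                   label, owner[at + 1L], .fmt_clock(at)), call. = FALSE)
    }
    owner[mins + 1L] <<- label
  }
  claim(s$sleep_onset, s$sleep_duration, "sleep window")
  b <- s$bout_plan
  if (nrow(b)) for (i in seq_len(nrow(b)))
    claim(b$start[i], as.integer(b$duration[i]), sprintf("bout[%d]", i))
  nw <- s$nonwear_segments
  if (nrow(nw)) for (i in seq_len(nrow(nw)))
    claim(nw$start[i], as.integer(nw$duration[i]),
          sprintf("nonwear[%d]", i))
  invisible(TRUE)
}

#' @export
print.activity_schedule <- function(x, ...) {
  cat(sprintf(
    "<activity_schedule> sleep %s + %d min (eff %.0f%%), %d bout(s), %d non-wear gap(s)\n",
    .fmt_clock(x$sleep_onset), x$sleep_duration, 100 * x$sleep_efficiency,
    nrow(x$bout_plan), nrow(x$nonwear_segments)))
  invisible(x)
}

# Scale a schedule by a group/individual effect:
# intensity multiplier on wake levels and bouts, duration multiplier on bouts.
.scale_schedule <- function(s, intensity = 1, bout_duration = 1) {
  s$wake_intensity_levels$intensity <-
    s$wake_intensity_levels$intensity * intensity
  if (nrow(s$bout_plan)) {
    s$bout_plan$intensity <- s$bout_plan$intensity * intensity
    s$bout_plan$duration <- pmax(1, round(s$bout_plan$duration * bout_duration))
  }
  .check_schedule_overlap(s)
  s
}
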