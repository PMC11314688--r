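# Raw signal -> calibrated 5-s ENMO epochs -> non-wear handling ->
# wear-validity screening.

#' Compute 5-s ENMO epochs from a raw recording
#'
#' Per sample, ENMO = max(0, sqrt(x^2 + y^2 + z^2) - 1 g); the epoch value
#' is the mean of sample ENMO over each epoch, in mg. Partial epochs at the
#' recording edges are dropped.
#'
#' @param rec a [triaxial_recording()].
#' @param cal optional `calibration_result` applied first.
#' @param epoch_length epoch length in seconds.
#' @return an [epoch_series()] (all epochs flagged `"wear"`), carrying the
#'   per-epoch z-angle of the calibrated signal.
#' @export
compute_enmo_epochs <- function(rec, cal = NULL,
                                epoch_length = EPOCH_LENGTH_DEFAULT) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (!is.null(cal)) rec <- apply_calibration(rec, cal)
  spe <- rec$sample_rate * epoch_length
  if (spe %% 1 != 0)
    stop("sample_rate x epoch_length must be an integer number of samples")
  spe <- as.integer(spe)
  # align the first epoch to the epoch grid
  lead <- (-rec$start_sec) %% epoch_length
  skip <- as.integer(round(lead * rec$sample_rate))
  d <- rec$data
  if (skip > 0) d <- d[-seq_len(skip), , drop = FALSE]
  ne <- nrow(d) %/% spe
  if (ne == 0L) stop("recording shorter than one epoch")
  d <- d[seq_len(ne * spe), , drop = FALSE]
  enmo_s <- pmax(0, sqrt(rowSums(d^2)) - 1) * 1000
  enmo <- colMeans(matrix(enmo_s, nrow = spe))
  ang <- colMeans(matrix(.z_angle_samples(d), nrow = spe))
  epoch_series(rec$id, enmo, epoch_length = epoch_length,
               start_sec = rec$start_sec + lead, angle = ang)
}

#' Detect non-wear segments
#'
#' A 15-min block is flagged as non-wear when, over a 60-min window centred
#' on it, at least two of the three axes show SD below `sd_crit_g` and a
#' value range below `range_crit_g`. Adjacent flagged blocks are merged and
#' each run is extended outward over neighbouring blocks that are
#' themselves low-variance, so short non-wear gaps are recovered at close
#' to their true extent.
#'
#' For epoch-only input (no per-axis signal) the same block/window logic is
#' applied to the ENMO series (thresholds in mg), a documented surrogate
#' recorded in the result's `method` attribute.
#'
#' @param x a [triaxial_recording()] or [epoch_series()].
#' @param block_sec block length, seconds (default 900).
#' @param window_sec centred window length, seconds (default 3600).
#' @param sd_crit_g,range_crit_g per-axis thresholds in g (raw input).
#' @param sd_crit_mg,range_crit_mg ENMO thresholds in mg (epoch input; near-zero variance, since an unworn device produces an essentially constant signal while even motionless sleep retains a few mg of noise).
#' @param ... passed between methods.
#' @return data frame with `start_sec`, `end_sec` (one row per segment) and
#'   attribute `method` (`"axis"` or `"enmo_surrogate"`).
#' @export
detect_nonwear <- function(x, ...) UseMethod("detect_nonwear")

.nonwear_blocks <- function(stat_fun, n_units, units_per_block,
                            units_per_window) {
  nb <- n_units %/% units_per_block
  if (nb == 0L) return(integer())
  half <- units_per_window %/% 2L
  flagged <- logical(nb)
  own_ok <- logical(nb)
  for (b in seq_len(nb)) {
    centre <- (b - 1L) * units_per_block + units_per_block %/% 2L
    win <- max(1L, centre - half):min(n_units, centre + half)
    flagged[b] <- stat_fun(win)
    own <- ((b - 1L) * units_per_block + 1L):(b * units_per_block)
    own_ok[b] <- stat_fun(own)
  }
  # extend flagged runs over adjacent blocks that are quiet on their own
  out <- flagged
  repeat {
    grow <- (!out) & own_ok &
      (c(FALSE, out[-nb]) | c(out[-1], FALSE))
    if (!any(grow)) break
    out <- out | grow
  }
  which(out)
}

.blocks_to_segments <- function(blocks, block_sec, start_sec) {
  if (!length(blocks))
    return(data.frame(start_sec = numeric(), end_sec = numeric()))
  # consecutive block ids form one segment
  grp <- cumsum(c(1L, diff(blocks) != 1L))
  do.call(rbind, lapply(split(blocks, grp), function(bs) data.frame(
    start_sec = start_sec + (min(bs) - 1L) * block_sec,
    end_sec = start_sec + max(bs) * block_sec)))
}

#' @rdname detect_nonwear
#' @export
detect_nonwear.triaxial_recording <- function(x, block_sec = 900,
                                              window_sec = 3600,
                                              sd_crit_g = 0.013,
                                              range_crit_g = 0.050, ...) {
  if (nrow(x$data) / x$sample_rate < window_sec)
    stop("recording shorter than the non-wear detection window")
  d <- x$data
  test <- function(idx) {
    sds <- apply(d[idx, , drop = FALSE], 2, sd)
    rngs <- apply(d[idx, , drop = FALSE], 2, function(v) diff(range(v)))
    sum(sds < sd_crit_g & rngs < range_crit_g) >= 2L
  }
  upb <- as.integer(block_sec * x$sample_rate)
  upw <- as.integer(window_sec * x$sample_rate)
  blocks <- .nonwear_blocks(test, nrow(d), upb, upw)
  seg <- .blocks_to_segments(blocks, block_sec, x$start_sec)
  attr(seg, "method") <- "axis"
  seg
}

#' @rdname detect_nonwear
#' @export
detect_nonwear.epoch_series <- function(x, block_sec = 900,
                                        window_sec = 3600,
                                        sd_crit_mg = 1,
                                        range_crit_mg = 5, ...) {
  if (length(x$enmo) * x$epoch_length < window_sec)
    stop("series shorter than the non-wear detection window")
  e <- x$enmo
  test <- function(idx) {
    v <- e[idx]
    sd(v) < sd_crit_mg && diff(range(v)) < range_crit_mg
  }
  upb <- as.integer(block_sec / x$epoch_length)
  upw <- as.integer(window_sec / x$epoch_length)
  blocks <- .nonwear_blocks(test, length(e), upb, upw)
  seg <- .blocks_to_segments(blocks, block_sec, x$start_sec)
  attr(seg, "method") <- "enmo_surrogate"
  message("detect_nonwear: no per-axis signal available; ",
          "using ENMO-variance surrogate")
  seg
}

#' Flag epochs covered by non-wear segments
#' @param epochs an [epoch_series()].
#' @param segments data frame with `start_sec`, `end_sec`.
#' @return the series with covered epochs flagged `"nonwear"`.
#' @export
flag_nonwear <- function(epochs, segments) {
  stopifnot(inherits(epochs, "epoch_series"))
  if (!nrow(segments)) return(epochs)
  t0 <- epochs$start_sec + (seq_along(epochs$enmo) - 1) * epochs$epoch_length
  for (i in seq_len(nrow(segments)))
    epochs$flag[t0 >= segments$start_sec[i] &
                  t0 < segments$end_sec[i]] <- "nonwear"
  epochs
}

#' Impute non-wear epochs from the same time of day on other days
#'
#' Each non-wear epoch's value is replaced by the mean of worn epochs in
#' the same time-of-day slot on the participant's other days, and flagged
#' `"imputed"`. Slots that are worn on no day are left unimputed (the
#' participant then fails the 15-min slot-coverage rule).
#'
#' @param epochs an [epoch_series()] with non-wear flagged.
#' @return the imputed series. Pre-imputation wear is still identifiable:
#'   only originally worn epochs carry flag `"wear"`.
#' @export
impute_nonwear <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_series"))
  inval <- epochs$flag == "nonwear"
  if (!any(inval)) return(epochs)
  slot <- epoch_slot_index(epochs)
  ok <- epochs$flag == "wear"
  if (!any(ok)) stop("no worn epochs to impute from")
  sums <- tapply(epochs$enmo[ok], slot[ok], sum)
  cnts <- tapply(rep(1, sum(ok)), slot[ok], sum)
  slot_mean <- setNames(as.numeric(sums / cnts), names(sums))
  key <- as.character(slot[inval])
  repl <- slot_mean[key]
  can <- !is.na(repl)
  idx <- which(inval)[can]
  epochs$enmo[idx] <- repl[can]
  epochs$flag[idx] <- "imputed"
  epochs
}

#' Apply the study inclusion rules to a participant
#'
#' A day is valid when its pre-imputation wear exceeds 16 h. A participant
#' is included when the post-calibration error is at most 10 mg, at least
#' 3 days are valid, and every 15-min period of the 24-h cycle is worn on
#' at least one day.
#'
#' @param epochs an [epoch_series()] with flags (before or after
#'   imputation; imputed epochs do not count as wear).
#' @param cal a `calibration_result`, a numeric post-calibration error in
#'   mg, or `NULL` (treated as 0 mg, e.g. pre-computed epoch input).
#' @param min_valid_days,min_wear_hours,max_cal_error_mg rule thresholds.
#' @return An object of class `wear_validation`: `valid_days`,
#'   `day_wear_hours`, `covered_15min_slots` (of 96), `included`,
#'   `exclusion_reason` (`"calibration"`, `"few_valid_days"`,
#'   `"slot_coverage"` or `"none"`).
#' @export
validate_wear <- function(epochs, cal = NULL, min_valid_days = 3,
                          min_wear_hours = 16, max_cal_error_mg = 10) {
  stopifnot(inherits(epochs, "epoch_series"))
  post_error <- if (is.null(cal)) 0 else
    if (inherits(cal, "calibration_result")) cal$post_error else as.numeric(cal)
  worn <- epochs$flag == "wear"
  day <- epoch_day_index(epochs)
  wear_h <- tapply(worn, day, sum) * epochs$epoch_length / 3600
  valid <- wear_h > min_wear_hours
  slot15 <- (epoch_slot_index(epochs) * epochs$epoch_length) %/% 900L
  covered <- length(unique(slot15[worn]))
  reason <- if (!is.na(post_error) && post_error > max_cal_error_mg)
    "calibration"
  else if (sum(valid) < min_valid_days) "few_valid_days"
  else if (covered < 96L) "slot_coverage"
  else "none"
  structure(list(valid_days = as.integer(sum(valid)),
                 day_wear_hours = setNames(as.numeric(wear_h),
                                           names(wear_h)),
                 valid_day_ids = as.integer(names(wear_h))[valid],
                 covered_15min_slots = as.integer(covered),
                 post_error = post_error,
                 included = reason == "none",
                 exclusion_reason = reason),
            class = "wear_validation")
}

#' @export
print.wear_validation <- function(x, ...) {
  cat(sprintf(
    "<wear_validation> %s (reason: %s)  valid days %d, slots %d/96, cal error %.1f mg\n",
    if (x$included) "INCLUDED" else "EXCLUDED", x$exclusion_reason,
    x$valid_days, x$covered_15min_slots, x$post_error))
  invisible(x)
}
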