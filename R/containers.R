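#' Triaxial wrist-acceleration recording
#'
#' Container for a regularly sampled three-axis acceleration signal in
#' gravitational units (g). Timestamps are implicit: sample `i` starts at
#' `start_sec + (i - 1) / sample_rate` seconds from midnight of recording
#' day 1.
#'
#' @param id participant identifier.
#' @param data numeric matrix with columns `x`, `y`, `z` in g.
#' @param sample_rate sampling frequency in Hz.
#' @param start_sec recording start, seconds from midnight of day 1.
#' @return An object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(id, data, sample_rate, start_sec = 0) {
  data <- as.matrix(data)
  if (ncol(data) != 3L) stop("`data` must have three axis columns")
  if (nrow(data) == 0L) stop("empty recording")
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  colnames(data) <- c("x", "y", "z")
  structure(
    list(id = id, data = data, sample_rate = sample_rate,
         start_sec = start_sec),
    class = "triaxial_recording"
  )
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> id=%s  %d samples @ %g Hz  (%.2f h)\n",
              x$id, nrow(x$data), x$sample_rate,
              nrow(x$data) / x$sample_rate / 3600))
  invisible(x)
}

#' ENMO epoch series
#'
#' Container for a per-epoch ENMO (Euclidean Norm Minus One, negatives
#' truncated to zero) series in mg, with a wear flag per epoch and an
#' optional per-epoch z-angle (degrees) carried from the raw signal.
#'
#' @param id participant identifier.
#' @param enmo numeric vector of per-epoch ENMO values, mg.
#' @param flag character vector, one of `"wear"`, `"nonwear"`, `"imputed"`.
#' @param epoch_length epoch length in seconds (default 5).
#' @param start_sec series start, seconds from midnight of day 1.
#' @param angle optional numeric vector of per-epoch z-angles in degrees.
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(id, enmo, flag = rep("wear", length(enmo)),
                         epoch_length = EPOCH_LENGTH_DEFAULT, start_sec = 0,
                         angle = NULL) {
  if (any(enmo < 0, na.rm = TRUE)) stop("ENMO values must be non-negative")
  if (length(flag) != length(enmo)) stop("flag/enmo length mismatch")
  bad <- setdiff(unique(flag), c("wear", "nonwear", "imputed"))
  if (length(bad)) stop("unknown flag value(s): ", paste(bad, collapse = ", "))
  if (!is.null(angle) && length(angle) != length(enmo))
    stop("angle/enmo length mismatch")
  structure(
    list(id = id, enmo = as.numeric(enmo), flag = flag,
         epoch_length = as.integer(epoch_length),
         start_sec = start_sec, angle = angle),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> id=%s  %d x %ds epochs (%.2f days)  wear %.1f%%\n",
    x$id, length(x$enmo), x$epoch_length,
    length(x$enmo) * x$epoch_length / 86400,
    100 * mean(x$flag != "nonwear")))
  invisible(x)
}

n_epochs_per_day <- function(x) as.integer(86400 / x$epoch_length)

#' Day index (1-based) of each epoch
#' @param x an `epoch_series`.
#' @return integer vector of calendar-day indices (midnight to midnight).
#' @keywords internal
epoch_day_index <- function(x) {
  t0 <- x$start_sec + (seq_along(x$enmo) - 1L) * x$epoch_length
  as.integer(t0 %/% 86400) + 1L
}

#' Within-day epoch slot (0-based) of each epoch
#' @keywords internal
epoch_slot_index <- function(x) {
  t0 <- x$start_sec + (seq_along(x$enmo) - 1L) * x$epoch_length
  as.integer((t0 %% 86400) %/% x$epoch_length)
}

#' Split an epoch series into complete calendar days
#'
#' @param x an `epoch_series` starting at midnight.
#' @return list of `epoch_series`, one per complete day; a trailing partial
#'   day is dropped.
#' @export
split_days <- function(x) {
  stopifnot(inherits(x, "epoch_series"))
  if (x$start_sec %% 86400 != 0)
    stop("split_days() expects a series starting at midnight")
  epd <- n_epochs_per_day(x)
  nd <- length(x$enmo) %/% epd
  lapply(seq_len(nd), function(d) {
    i <- ((d - 1L) * epd + 1L):(d * epd)
    epoch_series(x$id, x$enmo[i], x$flag[i], x$epoch_length,
                 start_sec = (d - 1L) * 86400,
                 angle = if (!is.null(x$angle)) x$angle[i])
  })
}

# ---- plain-text IO -------------------------------------------------------

# Fixed origin date used when materialising ISO-8601 timestamps (a Monday).
.wristmx_origin <- function() as.POSIXct("2019-01-07 00:00:00", tz = "UTC")

#' Write / read a raw triaxial recording as long CSV
#'
#' Columns: `timestamp` (ISO-8601, UTC), `x`, `y`, `z` in g.
#' @param rec a `triaxial_recording`.
#' @param path file path.
#' @export
write_raw_csv <- function(rec, path) {
  ts <- .wristmx_origin() + rec$start_sec +
    (seq_len(nrow(rec$data)) - 1) / rec$sample_rate
  df <- data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%OS3Z"),
                   x = rec$data[, 1], y = rec$data[, 2], z = rec$data[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raw_csv
#' @param path file path.
#' @param id participant identifier to attach.
#' @export
read_raw_csv <- function(path, id = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in ", path)
  dt <- diff(as.numeric(ts))
  if (any(dt <= 0)) stop("timestamps not strictly increasing in ", path)
  sr <- 1 / median(dt)
  # snap to the nominal device rate (timestamps carry ms precision)
  if (abs(sr - round(sr)) < 0.01) sr <- round(sr)
  start <- as.numeric(ts[1] - .wristmx_origin(), units = "secs")
  triaxial_recording(id, cbind(df$x, df$y, df$z),
                     sample_rate = sr, start_sec = start)
}

#' Write / read an ENMO epoch series as CSV
#'
#' Columns: `epoch_start` (ISO-8601, UTC), `enmo_mg`, `wear_flag`
#' (wear/nonwear/imputed) and, when available, `angle_z` in degrees.
#' @param x an `epoch_series`.
#' @param path file path.
#' @export
write_epoch_csv <- function(x, path) {
  ts <- .wristmx_origin() + x$start_sec +
    (seq_along(x$enmo) - 1) * x$epoch_length
  df <- data.frame(epoch_start = format(ts, "%Y-%m-%dT%H:%M:%SZ"),
                   enmo_mg = x$enmo, wear_flag = x$flag)
  if (!is.null(x$angle)) df$angle_z <- x$angle
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epoch_csv
#' @param id participant identifier to attach.
#' @export
read_epoch_csv <- function(path, id = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$epoch_start, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) stop("unparseable epoch timestamps in ", path)
  el <- as.integer(round(median(diff(as.numeric(ts)))))
  start <- as.numeric(ts[1] - .wristmx_origin(), units = "secs")
  epoch_series(id, df$enmo_mg, df$wear_flag, epoch_length = el,
               start_sec = start,
               angle = if ("angle_z" %in% names(df)) df$angle_z)
}
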