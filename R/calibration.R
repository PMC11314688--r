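# Auto-calibration of the raw signal to local gravity.
#
# Still 10-s windows (all three axis SDs below 13 mg) give candidate
# gravity vectors; per-axis offset and gain are then refined by iteratively
# reweighted least squares pulling still-window magnitudes towards 1 g.

.window_stats <- function(data, spw) {
  nw <- nrow(data) %/% spw
  if (nw == 0L) return(NULL)
  idx <- seq_len(nw * spw)
  out <- lapply(1:3, function(a) {
    m <- matrix(data[idx, a], nrow = spw)
    mu <- colMeans(m)
    sdv <- sqrt(pmax(0, (colSums(m^2) - spw * mu^2) / (spw - 1)))
    rng <- apply(m, 2, function(v) diff(range(v)))
    cbind(mean = mu, sd = sdv, range = rng)
  })
  list(mean = cbind(out[[1]][, 1], out[[2]][, 1], out[[3]][, 1]),
       sd = cbind(out[[1]][, 2], out[[2]][, 2], out[[3]][, 2]),
       range = cbind(out[[1]][, 3], out[[2]][, 3], out[[3]][, 3]))
}

#' Auto-calibrate a raw recording to local gravity
#'
#' Estimates per-axis offset and gain such that the magnitude of the
#' calibrated signal `(raw + offset) * gain` is 1 g during still periods.
#' Still periods are non-overlapping windows (default 10 s) in which all
#' three axis standard deviations fall below `sd_crit_g`. If too few still
#' points are found, or they do not span enough orientations to identify
#' the six parameters, the identity transform is returned with
#' `converged = FALSE`.
#'
#' @param rec a [triaxial_recording()].
#' @param still_window_sec still-window length, seconds.
#' @param sd_crit_g per-axis stillness criterion, g (default 0.013 = 13 mg).
#' @param min_still minimum number of still windows required.
#' @param min_spread_g minimum per-axis range of still orientations (g)
#'   required to fit gains.
#' @param tol convergence tolerance on the per-iteration offset/gain
#'   update, g.
#' @param max_iter maximum IRLS iterations.
#' @return An object of class `calibration_result`: `offset` (g), `gain`,
#'   `post_error` (mg), `pre_error` (mg), `n_still_points`, `converged`.
#' @export
autocalibrate <- function(rec, still_window_sec = 10, sd_crit_g = 0.013,
                          min_still = 10, min_spread_g = 0.3,
                          tol = 1e-5, max_iter = 1000) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (nrow(rec$data) == 0L) stop("empty recording")
  spw <- as.integer(round(still_window_sec * rec$sample_rate))
  ws <- .window_stats(rec$data, spw)
  identity_result <- function(P) {
    err <- if (!is.null(P) && nrow(P))
      1000 * mean(abs(sqrt(rowSums(P^2)) - 1)) else NA_real_
    structure(list(offset = c(0, 0, 0), gain = c(1, 1, 1),
                   post_error = err, pre_error = err,
                   n_still_points = if (is.null(P)) 0L else nrow(P),
                   converged = FALSE),
              class = "calibration_result")
  }
  if (is.null(ws)) return(identity_result(NULL))
  still <- rowSums(ws$sd < sd_crit_g) == 3L
  P <- ws$mean[still, , drop = FALSE]
  if (nrow(P) < min_still) return(identity_result(P))
  spread <- apply(P, 2, function(v) diff(range(v)))
  if (any(spread < min_spread_g)) return(identity_result(P))

  off <- c(0, 0, 0); gain <- c(1, 1, 1)
  pre_error <- mean(abs(sqrt(rowSums(P^2)) - 1))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    off0 <- off; gain0 <- gain
    cal <- sweep(sweep(P, 2, off, "+"), 2, gain, "*")
    nrm <- sqrt(rowSums(cal^2))
    target <- cal / nrm
    w <- pmin(1 / pmax(abs(nrm - 1), 1e-4), 1e4)
    for (a in 1:3) {
      fit <- stats::lm.wfit(cbind(1, cal[, a]), target[, a], w)
      b <- fit$coefficients[2]
      if (!is.finite(b) || b <= 0) next
      gain[a] <- gain[a] * b
      off[a] <- off[a] + fit$coefficients[1] / gain[a]
    }
    if (max(abs(off - off0), abs(gain - gain0)) < tol) {
      converged <- TRUE
      break
    }
  }
  cal <- sweep(sweep(P, 2, off, "+"), 2, gain, "*")
  post_error <- mean(abs(sqrt(rowSums(cal^2)) - 1))
  if (!all(gain > 0.5 & gain < 2)) return(identity_result(P))
  if (post_error > pre_error) return(identity_result(P))
  structure(list(offset = off, gain = gain,
                 post_error = 1000 * post_error,
                 pre_error = 1000 * pre_error,
                 n_still_points = nrow(P), converged = converged),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> offset=(%.4f, %.4f, %.4f) g  gain=(%.4f, %.4f, %.4f)\n  post-error %.2f mg from %d still points (converged: %s)\n",
    x$offset[1], x$offset[2], x$offset[3],
    x$gain[1], x$gain[2], x$gain[3],
    x$post_error, x$n_still_points, x$converged))
  invisible(x)
}

#' Apply a calibration to a raw recording
#' @param rec a [triaxial_recording()].
#' @param cal a `calibration_result`.
#' @return the calibrated recording: `(raw + offset) * gain`.
#' @export
apply_calibration <- function(rec, cal) {
  stopifnot(inherits(rec, "triaxial_recording"),
            inherits(cal, "calibration_result"))
  rec$data <- sweep(sweep(rec$data, 2, cal$offset, "+"), 2, cal$gain, "*")
  rec
}
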