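# Brute-force oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (flat loops, full sorts) and independent
# of the package's vectorised / compiled implementations.

oracle_mx_acc <- function(x, duration_min, el = 5) {
  n <- duration_min * 60 / el
  sort(x, decreasing = TRUE)[n]
}

oracle_mx_cont <- function(x, duration_min, el = 5, q = 0.25) {
  n <- duration_min * 60 / el
  k <- ceiling(q * n)
  best <- -Inf
  for (i in seq_len(length(x) - n + 1)) {
    v <- sort(x[i:(i + n - 1)])[k]
    if (v > best) best <- v
  }
  best
}

oracle_enmo_epochs <- function(data, sr, el = 5) {
  spe <- sr * el
  ne <- nrow(data) %/% spe
  out <- numeric(ne)
  for (e in seq_len(ne)) {
    s <- 0
    for (i in ((e - 1) * spe + 1):(e * spe)) {
      nrm <- sqrt(data[i, 1]^2 + data[i, 2]^2 + data[i, 3]^2)
      s <- s + max(0, nrm - 1) * 1000
    }
    out[e] <- s / spe
  }
  out
}

oracle_z_angle <- function(data, sr, el = 5) {
  spe <- sr * el
  ne <- nrow(data) %/% spe
  out <- numeric(ne)
  for (e in seq_len(ne)) {
    s <- 0
    for (i in ((e - 1) * spe + 1):(e * spe))
      s <- s + atan(data[i, 3] / sqrt(data[i, 1]^2 + data[i, 2]^2)) * 180 / pi
    out[e] <- s / spe
  }
  out
}

# one synthetic day (17280 epochs) as a bare numeric vector
random_day <- function(seed, n = 17280, rate = 1 / 20) {
  set.seed(seed)
  rexp(n, rate)
}

# epoch series with a given per-epoch value vector, starting at midnight
day_series <- function(enmo, id = "T", flag = NULL, angle = NULL) {
  if (is.null(flag)) flag <- rep("wear", length(enmo))
  epoch_series(id, enmo, flag, angle = angle)
}

# a still recording at a single fixed orientation
still_recording <- function(u = c(0, 0, 1), secs = 300, sr = 20) {
  triaxial_recording("S", matrix(rep(u, each = secs * sr), ncol = 3), sr)
}

# day where bin occupancy follows a power law: time in the 25-mg bin at
# mid-intensity m is proportional to m^exponent
power_law_day <- function(exponent, n_target = 17280, bin = 25,
                          max_mg = 4000) {
  mids <- seq(bin / 2, max_mg - bin / 2, by = bin)
  w <- mids^exponent
  counts <- round(n_target * w / sum(w))
  x <- rep(mids, counts)
  if (length(x) < n_target) x <- c(x, rep(mids[1], n_target - length(x)))
  x[seq_len(n_target)]
}

# per-epoch truth sleep-window mask for a generated participant
.sleep_mask_for_test <- function(gp) {
  t0 <- (seq_along(gp$data$enmo) - 1) * gp$data$epoch_length
  w <- gp$truth$sleep_windows
  mask <- rep(FALSE, length(t0))
  for (i in seq_len(nrow(w)))
    mask[t0 >= w$onset_sec[i] & t0 < w$offset_sec[i]] <- TRUE
  mask
}
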