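# Synthetic participant / cohort generator with planted ground truth.
#
# One RNG stream per participant, consumed in a fixed order regardless of
# output mode, so the ENMO epochs of a raw-mode run equal those of an
# epoch-mode run under the same seed.

.deg2rad <- function(d) d * pi / 180

#' Generate one synthetic participant
#'
#' Builds a minute-level plan from the schedule (sleep window, arousals,
#' bouts, non-wear gaps, shuffled filler blocks), expands it to 5-s ENMO
#' epochs with truncated-Gaussian noise and a per-epoch wrist z-angle, and
#' optionally expands epochs into a raw triaxial signal (sleep = gravity on
#' a stable per-night orientation plus small jitter; non-wear = exactly
#' constant signal).
#'
#' @param schedule an [activity_schedule()].
#' @param days number of simulated days (>= 1).
#' @param mode `"epoch"` (default) for a 5-s [epoch_series()], `"raw"` for a
#'   [triaxial_recording()].
#' @param seed integer; fully determines the output.
#' @param id participant identifier.
#' @param sample_rate Hz, raw mode only (5 * sample_rate must be integer).
#' @param calibration_offset,calibration_gain per-axis miscalibration
#'   planted into raw output; the true signal equals
#'   `(raw + offset) * gain`.
#' @param sample_noise_sd per-sample isotropic noise in g, raw mode.
#' @return list with elements `data` (the series/recording) and `truth`
#'   (a `ground_truth` list: planted sleep windows, bouts, non-wear
#'   segments, realized daily mean ENMO, and per-day category minutes).
#' @export
generate_participant <- function(schedule, days = 7, mode = c("epoch", "raw"),
                                 seed = 1, id = "P1", sample_rate = 20,
                                 calibration_offset = c(0, 0, 0),
                                 calibration_gain = c(1, 1, 1),
                                 sample_noise_sd = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "activity_schedule"), days >= 1)
  if (mode == "raw" && (sample_rate * 5) %% 1 != 0)
    stop("raw mode needs 5 * sample_rate to be an integer")
  set.seed(as.integer(seed))
  s <- schedule
  M <- days * MIN_PER_DAY

  # minute-level plan ------------------------------------------------------
  type <- rep("wake", M)            # wake | sleep | arousal | nonwear
  inten <- rep(NA_real_, M)         # wake-level target intensity, mg
  night <- rep(NA_integer_, M)      # window id for sleep orientation

  # sleep windows n = 0..days (n = 0 is the partial first morning)
  win <- do.call(rbind, lapply(0:days, function(n) {
    a <- s$sleep_onset + MIN_PER_DAY * (n - 1L)
    data.frame(night = n, start = a, end = a + s$sleep_duration)
  }))
  win <- win[win$end > 0 & win$start < M, , drop = FALSE]
  win$cstart <- pmax(win$start, 0L)
  win$cend <- pmin(win$end, M)
  win$complete <- win$start >= 0 & win$end <= M
  for (i in seq_len(nrow(win))) {
    mins <- (win$cstart[i] + 1L):win$cend[i]
    type[mins] <- "sleep"
    night[mins] <- win$night[i]
  }
  # arousals: consolidated wake episodes (10-20 min) inside each window,
  # kept clear of the edges and of each other so the sleep runs between
  # them remain long, as in real sleep architecture
  margin <- 31L
  for (i in seq_len(nrow(win))) {
    wlen <- win$cend[i] - win$cstart[i]
    target <- round((1 - s$sleep_efficiency) * wlen)
    lo <- win$cstart[i] + margin
    hi <- win$cend[i] - margin
    placed <- 0L; tries <- 0L
    while (placed < target && tries < 200L && hi - lo > 20L) {
      len <- min(sample(10:20, 1L), target - placed + 5L)
      at <- sample(lo:(hi - len), 1L)
      guard <- max(win$cstart[i] + 1L, at - margin + 1L):
        min(win$cend[i], at + len + margin)
      if (all(type[guard] == "sleep")) {
        type[(at + 1L):(at + len)] <- "arousal"
        inten[(at + 1L):(at + len)] <- s$arousal_intensity
        placed <- placed + len
      }
      tries <- tries + 1L
    }
  }
  # planted bouts and non-wear gaps, repeated daily
  bouts <- s$bout_plan
  truth_bouts <- NULL
  for (d in seq_len(days)) {
    off <- (d - 1L) * MIN_PER_DAY
    if (nrow(bouts)) for (i in seq_len(nrow(bouts))) {
      idx <- off + bouts$start[i] + seq_len(as.integer(bouts$duration[i]))
      idx <- idx[idx <= M]
      type[idx] <- "bout"
      inten[idx] <- bouts$intensity[i]
      truth_bouts <- rbind(truth_bouts, data.frame(
        day = d, start_sec = (off + bouts$start[i]) * 60,
        end_sec = (off + bouts$start[i] + bouts$duration[i]) * 60,
        intensity = bouts$intensity[i]))
    }
    nw <- s$nonwear_segments
    if (nrow(nw)) for (i in seq_len(nrow(nw))) {
      idx <- off + nw$start[i] + seq_len(as.integer(nw$duration[i]))
      idx <- idx[idx <= M]
      type[idx] <- "nonwear"
      inten[idx] <- 0
    }
  }
  # filler: allocate remaining wake minutes to intensity levels, block-wise
  lv <- s$wake_intensity_levels
  for (d in seq_len(days)) {
    idx <- which(type == "wake" &
                   (seq_len(M) - 1L) %/% MIN_PER_DAY == (d - 1L))
    L <- length(idx)
    if (!L) next
    alloc <- floor(L * lv$minutes / sum(lv$minutes))
    rem <- L - sum(alloc)
    if (rem > 0) {
      top <- order(lv$minutes, decreasing = TRUE)
      alloc[top[seq_len(rem)]] <- alloc[top[seq_len(rem)]] + 1L
    }
    blocks <- list()
    for (k in seq_len(nrow(lv))) {
      if (!alloc[k]) next
      blen <- if (lv$intensity[k] < 40) s$inactive_block_min else
        s$active_block_min
      n_full <- alloc[k] %/% blen
      sizes <- c(rep(blen, n_full), alloc[k] - n_full * blen)
      sizes <- sizes[sizes > 0]
      blocks <- c(blocks, lapply(sizes, function(sz)
        rep(lv$intensity[k], sz)))
    }
    blocks <- blocks[sample.int(length(blocks))]
    inten[idx] <- unlist(blocks)[seq_len(L)]
  }

  # per-night orientations -------------------------------------------------
  nn <- nrow(win)
  night_theta <- sample(c(-1, 1), nn, replace = TRUE) * runif(nn, 20, 70)
  night_phi <- runif(nn, 0, 360)
  names(night_theta) <- names(night_phi) <- as.character(win$night)

  # epoch expansion ---------------------------------------------------------
  epm <- 60L %/% EPOCH_LENGTH_DEFAULT        # 12 epochs per minute
  N <- M * epm
  e_type <- rep(type, each = epm)
  e_inten <- rep(inten, each = epm)
  e_night <- rep(night, each = epm)
  noise <- rnorm(N, 0, s$noise_sd)
  sleep_draw <- rnorm(N, s$sleep_enmo_mean, s$sleep_enmo_sd)
  ang_jit <- rnorm(N, 0, s$sleep_angle_jitter_sd)
  az_jit <- rnorm(N, 0, 3 * s$sleep_angle_jitter_sd)
  ang_wake <- runif(N, -60, 60)
  az_wake <- runif(N, 0, 360)

  enmo <- numeric(N)
  ang <- numeric(N)
  az <- numeric(N)
  is_sleep <- e_type == "sleep"
  is_nw <- e_type == "nonwear"
  is_wake <- !is_sleep & !is_nw
  enmo[is_wake] <- pmax(0, e_inten[is_wake] + noise[is_wake])
  enmo[is_sleep] <- pmax(0, sleep_draw[is_sleep])
  enmo[is_nw] <- 0
  ang[is_wake] <- ang_wake[is_wake]
  az[is_wake] <- az_wake[is_wake]
  key <- as.character(e_night[is_sleep])
  ang[is_sleep] <- night_theta[key] + ang_jit[is_sleep]
  # wrist azimuth drifts more than elevation during sleep; the z-angle is
  # azimuth-free, so this only affects the raw axes (non-wear detection)
  az[is_sleep] <- night_phi[key] + az_jit[is_sleep]
  ang[is_sleep] <- pmax(-89, pmin(89, ang[is_sleep]))
  ang[is_nw] <- 90
  az[is_nw] <- 0
  flag <- ifelse(is_nw, "nonwear", "wear")

  # ground truth ------------------------------------------------------------
  dayix <- rep(seq_len(days), each = MIN_PER_DAY * epm)
  minday <- rep(seq_len(days), each = MIN_PER_DAY)
  cat_min <- data.frame(
    day = seq_len(days),
    sleep_window = tapply(type %in% c("sleep", "arousal"), minday, sum),
    inactive = tapply(type %in% c("wake", "bout") & inten < 40, minday, sum),
    light = tapply(type %in% c("wake", "bout") & inten >= 40 & inten <= 100,
                   minday, sum),
    mvpa = tapply(type %in% c("wake", "bout") & inten > 100, minday, sum),
    nonwear = tapply(type == "nonwear", minday, sum),
    row.names = NULL)
  nw_rle <- rle(type == "nonwear")
  nw_end <- cumsum(nw_rle$lengths)
  nw_seg <- if (any(nw_rle$values)) data.frame(
    start_sec = (nw_end - nw_rle$lengths)[nw_rle$values] * 60,
    end_sec = nw_end[nw_rle$values] * 60) else
      data.frame(start_sec = numeric(), end_sec = numeric())
  truth <- structure(list(
    id = id, days = days,
    sleep_windows = data.frame(night = win$night,
                               onset_sec = win$start * 60,
                               offset_sec = win$end * 60,
                               complete = win$complete),
    bouts = truth_bouts,
    nonwear = nw_seg,
    daily_mean_enmo = as.numeric(tapply(enmo, dayix, mean)),
    category_minutes = cat_min,
    schedule = s), class = "ground_truth")

  if (mode == "epoch") {
    data <- epoch_series(id, enmo, flag, start_sec = 0, angle = ang)
  } else {
    spe <- as.integer(sample_rate * 5)
    mag <- 1 + rep(enmo, each = spe) / 1000
    th <- .deg2rad(rep(ang, each = spe))
    ph <- .deg2rad(rep(az, each = spe))
    xyz <- cbind(x = mag * cos(th) * cos(ph),
                 y = mag * cos(th) * sin(ph),
                 z = mag * sin(th))
    if (sample_noise_sd > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), 0, sample_noise_sd),
                          ncol = 3)
    # plant miscalibration: downstream calibration is (raw + offset) * gain
    xyz <- sweep(sweep(xyz, 2, calibration_gain, "/"), 2,
                 calibration_offset, "-")
    data <- triaxial_recording(id, xyz, sample_rate, start_sec = 0)
  }
  list(data = data, truth = truth)
}

#' Per-group covariate distribution presets
#'
#' Default sampling distributions for the seven adjustment covariates,
#' calibrated to the characteristics of a secondary-care type 2 diabetes
#' cohort with and without active foot ulcers: the ulcer group is younger,
#' more often male and white, has longer diabetes duration and slightly
#' higher BMI.
#' @return named list (one element per group) of distribution parameters.
#' @export
default_covariate_params <- function() {
  list(
    nonDFU = list(age = c(64.3, 8.2), sex_male = 0.643, bmi = c(31.0, 5.1),
                  ethnicity_white = 0.841, cvd_yes = 0.551,
                  diabetes_duration = c(10.3, 7.5), wear_days = c(6.9, 0.4)),
    DFU = list(age = c(58.9, 8.9), sex_male = 0.882, bmi = c(32.7, 4.8),
               ethnicity_white = 0.941, cvd_yes = 0.412,
               diabetes_duration = c(15.4, 9.6), wear_days = c(6.8, 0.7)))
}

.draw_covariates <- function(n, p) {
  data.frame(
    age = round(pmin(75, pmax(18, rnorm(n, p$age[1], p$age[2]))), 1),
    sex = ifelse(rbinom(n, 1, p$sex_male) == 1, "male", "female"),
    bmi = round(pmin(45, pmax(18, rnorm(n, p$bmi[1], p$bmi[2]))), 1),
    ethnicity = ifelse(rbinom(n, 1, p$ethnicity_white) == 1,
                       "white", "non-white"),
    cvd = ifelse(rbinom(n, 1, p$cvd_yes) == 1, "yes", "no"),
    diabetes_duration = round(pmax(0.5, rnorm(n, p$diabetes_duration[1],
                                              p$diabetes_duration[2])), 1))
}

#' Cohort generation settings
#'
#' @param n_per_group named integer vector: participants per group label.
#' @param group_effects named list (same labels) of
#'   `list(intensity =, bout_duration =)` multiplicative effects applied to
#'   each participant's schedule. Defaults emulate a foot-ulcer group with
#'   ~22% lower wake intensity and half-length activity bouts, landing group
#'   activity volumes near 22 vs 17 mg.
#' @param days days of wear per participant.
#' @param mode `"epoch"` or `"raw"` (see [generate_participant()]).
#' @param schedule base [activity_schedule()] shared by all participants.
#' @param between_subject_sd SD of the log-normal individual intensity
#'   multiplier.
#' @param covariate_params see [default_covariate_params()].
#' @param sample_rate,calibration_offset,calibration_gain raw-mode settings.
#' @param seed integer; fully determines the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(nonDFU = 6, DFU = 6),
                        group_effects = list(
                          nonDFU = list(intensity = 1, bout_duration = 1),
                          DFU = list(intensity = 0.78, bout_duration = 0.5)),
                        days = 7, mode = "epoch",
                        schedule = activity_schedule(),
                        between_subject_sd = 0.12,
                        covariate_params = default_covariate_params(),
                        sample_rate = 20,
                        calibration_offset = c(0, 0, 0),
                        calibration_gain = c(1, 1, 1),
                        seed = 1) {
  if (days < 1) stop("days must be >= 1")
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1")
  if (is.null(names(n_per_group))) stop("n_per_group must be named")
  extra <- setdiff(names(group_effects), names(n_per_group))
  if (length(extra))
    stop("unknown group label in group_effects: ",
         paste(extra, collapse = ", "))
  missing_g <- setdiff(names(n_per_group), names(group_effects))
  if (length(missing_g))
    stop("group_effects missing for group(s): ",
         paste(missing_g, collapse = ", "))
  cp <- covariate_params
  for (g in names(n_per_group))
    if (is.null(cp[[g]])) cp[[g]] <- default_covariate_params()[[1]]
  structure(list(n_per_group = n_per_group, group_effects = group_effects,
                 days = as.integer(days), mode = mode, schedule = schedule,
                 between_subject_sd = between_subject_sd,
                 covariate_params = cp, sample_rate = sample_rate,
                 calibration_offset = calibration_offset,
                 calibration_gain = calibration_gain,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic two-group cohort
#'
#' Draws covariates per group, scales the base schedule by the group effect
#' and a log-normal individual factor, and generates each participant's
#' signal with its own derived seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `covariates` (data frame: id, group, the seven
#'   adjustment covariates), `data` (named list of series/recordings) and
#'   `truth` (named list of `ground_truth`), plus a `true_volume` column in
#'   a `truth_table` summarising each participant's realized mean ENMO.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)
  pseeds <- sample.int(.Machine$integer.max - 1L, n)
  indiv <- exp(rnorm(n, 0, spec$between_subject_sd))
  cov_list <- lapply(names(spec$n_per_group), function(g)
    .draw_covariates(spec$n_per_group[[g]], spec$covariate_params[[g]]))
  covs <- do.call(rbind, cov_list)
  ids <- sprintf("%s_%02d", groups, unlist(lapply(spec$n_per_group, seq_len)))
  covariates <- cbind(data.frame(id = ids, group = groups), covs)

  data <- list(); truth <- list()
  for (i in seq_len(n)) {
    ef <- spec$group_effects[[groups[i]]]
    sched_i <- .scale_schedule(spec$schedule,
                               intensity = ef$intensity * indiv[i],
                               bout_duration = ef$bout_duration)
    gp <- generate_participant(sched_i, days = spec$days, mode = spec$mode,
                               seed = pseeds[i], id = ids[i],
                               sample_rate = spec$sample_rate,
                               calibration_offset = spec$calibration_offset,
                               calibration_gain = spec$calibration_gain)
    gp$truth$group <- groups[i]
    gp$truth$intensity_effect <- ef$intensity
    data[[ids[i]]] <- gp$data
    truth[[ids[i]]] <- gp$truth
  }
  # scheduled non-wear reduces the wear-time covariate
  nw_min <- sum(spec$schedule$nonwear_segments$duration)
  covariates$wear_days <- round(spec$days * (1 - nw_min / MIN_PER_DAY), 2)
  truth_table <- data.frame(
    id = ids, group = groups,
    true_volume = vapply(truth, function(t) mean(t$daily_mean_enmo), 0),
    intensity_effect = vapply(truth, function(t) t$intensity_effect, 0),
    row.names = NULL)
  list(covariates = covariates, data = data, truth = truth,
       truth_table = truth_table)
}

#' Simulate a still-orientation recording for calibration testing
#'
#' A sequence of still postures (random unit orientations held for
#' `dwell_sec` each) at exactly 1 g plus small per-axis noise, distorted by
#' a planted per-axis offset and gain.
#'
#' @param n_orientations number of distinct still postures.
#' @param dwell_sec seconds held per posture.
#' @param sample_rate Hz.
#' @param noise_sd_g per-sample per-axis noise, g.
#' @param offset,gain planted miscalibration; the true signal equals
#'   `(raw + offset) * gain`.
#' @param seed integer seed.
#' @param id participant identifier.
#' @return list with `rec` (a [triaxial_recording()]) and `truth`
#'   (`offset`, `gain`).
#' @export
simulate_still_recording <- function(n_orientations = 30, dwell_sec = 60,
                                     sample_rate = 20, noise_sd_g = 0.003,
                                     offset = c(0, 0, 0), gain = c(1, 1, 1),
                                     seed = 1, id = "CAL") {
  set.seed(as.integer(seed))
  u <- matrix(rnorm(3 * n_orientations), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  spe <- as.integer(round(dwell_sec * sample_rate))
  xyz <- u[rep(seq_len(n_orientations), each = spe), , drop = FALSE]
  xyz <- xyz + matrix(rnorm(length(xyz), 0, noise_sd_g), ncol = 3)
  xyz <- sweep(sweep(xyz, 2, gain, "/"), 2, offset, "-")
  list(rec = triaxial_recording(id, xyz, sample_rate),
       truth = list(offset = offset, gain = gain))
}

#' Simulate participant-level outcomes from a known adjusted group contrast
#'
#' Light-weight cohort simulator for validating the statistical stage
#' without generating signal: covariates are drawn from the per-group
#' presets (so groups are genuinely confounded) and the outcome follows a
#' GLM with a known group contrast on the link scale.
#'
#' @param n_per_group named vector of group sizes.
#' @param group_means named or ordered vector of true adjusted outcome
#'   means (response scale, at zero-centred covariates), one per group.
#' @param family `"gaussian"` (identity link) or `"gamma"` (log link).
#' @param residual_sd Gaussian residual SD.
#' @param gamma_shape gamma shape parameter (smaller = more skewed).
#' @param covariate_effects named numeric vector of linear effects applied
#'   to centred covariates (identity scale; divided by the overall mean for
#'   the log link so effects stay comparable).
#' @param seed integer seed.
#' @return data frame of covariates + `outcome`, with attributes
#'   `true_difference` (first group minus second) and `true_group_means`.
#' @export
simulate_trial_outcomes <- function(n_per_group = c(nonDFU = 500, DFU = 500),
                                    group_means = c(22, 17),
                                    family = c("gaussian", "gamma"),
                                    residual_sd = 5, gamma_shape = 4,
                                    covariate_effects = c(
                                      age = -0.06, sex_male = 1.2,
                                      bmi = -0.12, ethnicity_white = 0.4,
                                      cvd_yes = -0.8,
                                      diabetes_duration = -0.05,
                                      wear_days = 0.3),
                                    seed = 1) {
  family <- match.arg(family)
  set.seed(as.integer(seed))
  cp <- default_covariate_params()
  groups <- names(n_per_group)
  dfs <- lapply(seq_along(groups), function(k) {
    g <- groups[k]
    p <- if (!is.null(cp[[g]])) cp[[g]] else cp[[1]]
    d <- .draw_covariates(n_per_group[[k]], p)
    d$wear_days <- round(pmin(8, pmax(3, rnorm(n_per_group[[k]],
                                               p$wear_days[1],
                                               p$wear_days[2]))), 2)
    d$group <- g
    d
  })
  d <- do.call(rbind, dfs)
  X <- cbind(age = d$age, sex_male = as.numeric(d$sex == "male"),
             bmi = d$bmi, ethnicity_white = as.numeric(d$ethnicity == "white"),
             cvd_yes = as.numeric(d$cvd == "yes"),
             diabetes_duration = d$diabetes_duration,
             wear_days = d$wear_days)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eff <- covariate_effects[colnames(X)]
  gm <- setNames(as.numeric(group_means), groups)
  if (family == "gaussian") {
    mu <- gm[d$group] + drop(Xc %*% eff)
    d$outcome <- rnorm(nrow(d), mu, residual_sd)
  } else {
    eta <- log(gm[d$group]) + drop(Xc %*% eff) / mean(gm)
    mu <- exp(eta)
    d$outcome <- rgamma(nrow(d), shape = gamma_shape,
                        rate = gamma_shape / mu)
  }
  d$group <- factor(d$group, levels = groups)
  rownames(d) <- NULL
  attr(d, "true_group_means") <- gm
  attr(d, "true_difference") <- unname(gm[1] - gm[2])
  d
}
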