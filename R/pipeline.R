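# Pipeline configuration and end-to-end orchestration:
# ingest -> wear validation -> imputation -> sleep -> daily metrics ->
# across-day aggregation -> covariate-adjusted group comparison.

#' Pipeline configuration
#'
#' Single structured container for every tunable constant of the pipeline;
#' round-trips losslessly through YAML via [write_config()] /
#' [read_config()].
#'
#' @param thresholds see [intensity_thresholds()].
#' @param hdcza see [hdcza_params()].
#' @param calibration list: `still_window_sec`, `sd_crit_g`, `min_still`,
#'   `min_spread_g`, `tol`, `max_iter`.
#' @param nonwear list: `block_sec`, `window_sec`, `sd_crit_g`,
#'   `range_crit_g`, `sd_crit_mg`, `range_crit_mg`, `detect_on_epochs`
#'   (run the ENMO surrogate even when the input already carries wear
#'   flags).
#' @param inclusion list: `min_valid_days`, `min_wear_hours`,
#'   `max_cal_error_mg`.
#' @param model list: `weights` ("proportional"/"equal"), `family`
#'   ("auto"/"gaussian"/"gamma"), `covariates` (adjustment set; the seven
#'   study covariates by default).
#' @param seed integer seed recorded in outputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = intensity_thresholds(),
                            hdcza = hdcza_params(),
                            calibration = list(still_window_sec = 10,
                                               sd_crit_g = 0.013,
                                               min_still = 10,
                                               min_spread_g = 0.3,
                                               tol = 1e-5, max_iter = 1000),
                            nonwear = list(block_sec = 900,
                                           window_sec = 3600,
                                           sd_crit_g = 0.013,
                                           range_crit_g = 0.050,
                                           sd_crit_mg = 1,
                                           range_crit_mg = 5,
                                           detect_on_epochs = FALSE),
                            inclusion = list(min_valid_days = 3,
                                             min_wear_hours = 16,
                                             max_cal_error_mg = 10),
                            model = list(weights = "proportional",
                                         family = "auto",
                                         covariates = .covariate_set),
                            seed = 1L) {
  structure(list(thresholds = thresholds, hdcza = hdcza,
                 calibration = calibration, nonwear = nonwear,
                 inclusion = inclusion, model = model,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    thresholds = do.call(intensity_thresholds, x$thresholds),
    hdcza = do.call(hdcza_params, x$hdcza),
    calibration = x$calibration, nonwear = x$nonwear,
    inclusion = x$inclusion, model = x$model, seed = x$seed)
  cfg
}

# Polynomial rolling hash of the YAML rendering: a stable fingerprint of
# the configuration for run logs.
config_hash <- function(config) {
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  bytes <- utf8ToInt(yaml::as.yaml(x))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Process one participant through ingest, sleep and metrics
#'
#' @param x a [triaxial_recording()] or [epoch_series()].
#' @param config a [pipeline_config()].
#' @return list: `validation` (`wear_validation`), `profile`
#'   (`participant_profile` or NULL if excluded), `sleep`
#'   (`sleep_summary` or NULL), `windows`, `wear_days` (mean daily worn
#'   hours before imputation, in days), `calibration`.
#' @export
process_participant <- function(x, config = pipeline_config()) {
  cal <- NULL
  if (inherits(x, "triaxial_recording")) {
    cb <- config$calibration
    cal <- autocalibrate(x, still_window_sec = cb$still_window_sec,
                         sd_crit_g = cb$sd_crit_g, min_still = cb$min_still,
                         min_spread_g = cb$min_spread_g, tol = cb$tol,
                         max_iter = cb$max_iter)
    nw <- config$nonwear
    seg <- detect_nonwear(x, block_sec = nw$block_sec,
                          window_sec = nw$window_sec,
                          sd_crit_g = nw$sd_crit_g,
                          range_crit_g = nw$range_crit_g)
    epochs <- compute_enmo_epochs(x, cal,
                                  config$thresholds$epoch_length)
    epochs <- flag_nonwear(epochs, seg)
  } else {
    epochs <- x
    if (config$nonwear$detect_on_epochs) {
      nw <- config$nonwear
      seg <- detect_nonwear(epochs, block_sec = nw$block_sec,
                            window_sec = nw$window_sec,
                            sd_crit_mg = nw$sd_crit_mg,
                            range_crit_mg = nw$range_crit_mg)
      epochs <- flag_nonwear(epochs, seg)
    }
  }
  inc <- config$inclusion
  validation <- validate_wear(epochs, cal,
                              min_valid_days = inc$min_valid_days,
                              min_wear_hours = inc$min_wear_hours,
                              max_cal_error_mg = inc$max_cal_error_mg)
  wear_days <- sum(validation$day_wear_hours) / 24
  if (!validation$included)
    return(list(validation = validation, profile = NULL, sleep = NULL,
                windows = NULL, wear_days = wear_days, calibration = cal))
  epochs <- impute_nonwear(epochs)
  windows <- detect_sleep_window(epochs, config$hdcza)
  labels <- classify_sustained_inactivity(epochs, windows, config$hdcza)
  slp <- if (any(windows$found))
    sleep_summary(windows, labels, epochs) else NULL
  days <- split_days(epochs)
  valid_ids <- validation$valid_day_ids
  profiles <- lapply(valid_ids[valid_ids <= length(days)], function(d) {
    daily_profile(days[[d]],
                  sleep = windows[windows$found, , drop = FALSE],
                  thr = config$thresholds, day = d)
  })
  profile <- aggregate_days(profiles)
  list(validation = validation, profile = profile, sleep = slp,
       windows = windows, wear_days = wear_days, calibration = cal)
}

#' Run the full pipeline over a cohort
#'
#' @param data named list of [epoch_series()] / [triaxial_recording()]
#'   objects (names = participant ids), or a directory containing
#'   `<id>_epochs.csv` files and `covariates.csv`.
#' @param covariates covariate data frame (`id`, `group`, age, sex, bmi,
#'   ethnicity, cvd, diabetes_duration); ignored when `data` is a
#'   directory with `covariates.csv`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, writes `metrics.csv`,
#'   `results.csv`, `exclusions.csv`, `sleep.csv`, a formatted report and
#'   a run log.
#' @return list: `metrics` (per-participant metric table), `results`
#'   (`comparison_table`), `exclusions`, `sleep`, `config_hash`.
#' @export
run_pipeline <- function(data, covariates = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  if (is.character(data) && length(data) == 1L) {
    dir <- data
    cov_path <- file.path(dir, "covariates.csv")
    if (is.null(covariates)) {
      if (!file.exists(cov_path)) stop("covariates.csv not found in ", dir)
      covariates <- read.csv(cov_path, stringsAsFactors = FALSE)
    }
    files <- list.files(dir, pattern = "_epochs\\.csv$", full.names = TRUE)
    if (!length(files)) stop("no *_epochs.csv files in ", dir)
    data <- lapply(files, function(f)
      read_epoch_csv(f, id = sub("_epochs\\.csv$", "", basename(f))))
    names(data) <- vapply(data, `[[`, "", "id")
  }
  if (is.null(covariates)) stop("covariate table required")
  ids <- names(data)
  rows <- list(); excl <- list(); slp_rows <- list()
  wear <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    res <- tryCatch(process_participant(data[[id]], config),
                    error = function(e)
                      stop("pipeline failed at participant ", id, ": ",
                           conditionMessage(e)))
    wear[id] <- res$wear_days
    if (is.null(res$profile)) {
      excl[[id]] <- data.frame(id = id,
                               reason = res$validation$exclusion_reason,
                               valid_days = res$validation$valid_days)
      next
    }
    row <- cbind(data.frame(id = id), profile_row(res$profile))
    row$sleep_duration <- if (!is.null(res$sleep))
      res$sleep$duration_min else NA_real_
    row$sleep_efficiency <- if (!is.null(res$sleep))
      res$sleep$efficiency_pct else NA_real_
    row$sleep_midpoint_sd <- if (!is.null(res$sleep))
      res$sleep$midpoint_sd_min else NA_real_
    rows[[id]] <- row
    if (!is.null(res$sleep))
      slp_rows[[id]] <- cbind(data.frame(id = id), res$sleep$nights)
  }
  if (!length(rows)) stop("no participants passed the inclusion rules")
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(), reason = character(),
               valid_days = integer())
  covariates <- covariates[covariates$id %in% metrics$id, , drop = FALSE]
  covariates$wear_days <- wear[covariates$id]
  outcome_cols <- setdiff(names(metrics), c("id", "valid_days"))
  # drop all-NA outcomes (e.g. sleep metrics when no windows were found)
  outcome_cols <- outcome_cols[vapply(outcome_cols, function(oc)
    !all(is.na(metrics[[oc]])), TRUE)]
  covariate_cols <- config$model$covariates
  if (is.null(covariate_cols)) covariate_cols <- .covariate_set
  results <- compare_groups(metrics, covariates, outcomes = outcome_cols,
                            covariate_cols = covariate_cols,
                            weights = config$model$weights)
  sleep_tab <- if (length(slp_rows)) do.call(rbind, slp_rows) else NULL
  hash <- config_hash(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    write.csv(exclusions, file.path(out_dir, "exclusions.csv"),
              row.names = FALSE)
    if (!is.null(sleep_tab))
      write.csv(sleep_tab, file.path(out_dir, "sleep.csv"),
                row.names = FALSE)
    writeLines(format_comparison(results),
               file.path(out_dir, "report.txt"))
    log <- c(sprintf("wristmx %s | R %s",
                     as.character(utils::packageVersion("wristmx")),
                     paste(R.version$major, R.version$minor, sep = ".")),
             sprintf("seed: %d", config$seed),
             sprintf("config hash: %s", hash),
             sprintf("included: %d  excluded: %d",
                     nrow(metrics), nrow(exclusions)),
             sprintf("excluded %s (%s)", exclusions$id, exclusions$reason))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(metrics = metrics, results = results, exclusions = exclusions,
       sleep = sleep_tab, config_hash = hash)
}

#' Write a simulated cohort to disk as pipeline input
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly. Writes `<id>_epochs.csv` (or `<id>_raw.csv`),
#'   `covariates.csv` and `truth.yaml`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$data)) {
    x <- cohort$data[[id]]
    if (inherits(x, "epoch_series"))
      write_epoch_csv(x, file.path(dir, paste0(id, "_epochs.csv")))
    else
      write_raw_csv(x, file.path(dir, paste0(id, "_raw.csv")))
  }
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  truth <- lapply(cohort$truth, function(t) list(
    group = t$group,
    daily_mean_enmo = t$daily_mean_enmo,
    sleep_windows = as.list(t$sleep_windows),
    nonwear = as.list(t$nonwear)))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Plot the mean hour-by-hour acceleration profile per group
#'
#' @param metrics_hourly named list mapping group label to a numeric
#'   24-vector of hourly mean ENMO (mg), e.g. averaged
#'   `participant_profile$hourly` values.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the plotted matrix.
#' @export
plot_hourly_profile <- function(metrics_hourly, ...) {
  m <- do.call(cbind, metrics_hourly)
  graphics::matplot(0:23, m, type = "l", lty = 1, lwd = 2,
                    xlab = "Hour of day", ylab = "Mean ENMO (mg)", ...)
  graphics::legend("topleft", legend = colnames(m), lty = 1, lwd = 2,
                   col = seq_len(ncol(m)), bty = "n")
  invisible(m)
}
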