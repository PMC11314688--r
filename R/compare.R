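# Covariate-adjusted two-group comparison: per-outcome GLMs (Gaussian
# identity vs gamma log, chosen by AIC), estimated marginal means with 95%
# CIs via emmeans, Wald p-values, and the symmetric percent difference.

.covariate_set <- c("age", "sex", "bmi", "ethnicity", "cvd",
                    "diabetes_duration", "wear_days")

#' Fit one outcome's generalized linear model
#'
#' Fits the outcome on group plus the adjustment covariates with a
#' Gaussian-identity GLM and, when every outcome value is positive, also a
#' gamma-log GLM; the family with the lower AIC is kept.
#'
#' @param data data frame containing `outcome_col`, `group` and the
#'   covariates; rows with missing values in any modelled column are
#'   dropped (count reported in the result).
#' @param outcome_col name of the outcome column.
#' @param covariates character vector of adjustment covariates (default:
#'   age, sex, BMI, ethnicity, cardiovascular disease, diabetes duration,
#'   accelerometer wear time). Use `character(0)` for an unadjusted fit.
#' @param family `"auto"` (AIC choice), `"gaussian"` or `"gamma"`.
#' @return list of class `outcome_fit`: `fit` (the chosen `glm`),
#'   `family`, `aic` (both families), `n`, `n_dropped`, `outcome`.
#' @export
fit_outcome <- function(data, outcome_col, covariates = .covariate_set,
                        family = c("auto", "gaussian", "gamma")) {
  family <- match.arg(family)
  cols <- c(outcome_col, "group", covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  d <- data[, cols, drop = FALSE]
  cc <- complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if (!is.factor(d$group)) d$group <- factor(d$group)
  if (nlevels(droplevels(d$group)) < 2L)
    stop("need at least two groups represented")
  constant <- vapply(covariates, function(v)
    length(unique(d[[v]])) < 2L, TRUE)
  if (any(constant)) {
    message("fit_outcome: dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    covariates <- covariates[!constant]
  }
  rhs <- paste(c("group", covariates), collapse = " + ")
  f <- as.formula(paste0("`", outcome_col, "` ~ ", rhs))
  if (nrow(d) <= length(covariates) + 2L)
    stop("too few rows to fit the model")
  fit_g <- glm(f, data = d, family = gaussian())
  if (any(!is.finite(coef(fit_g)))) {
    bad <- names(coef(fit_g))[!is.finite(coef(fit_g))]
    stop("singular design; collinear term(s): ", paste(bad, collapse = ", "))
  }
  aic <- c(gaussian = AIC(fit_g), gamma = NA_real_)
  fit <- fit_g; fam <- "gaussian-identity"
  want_gamma <- family %in% c("auto", "gamma")
  if (want_gamma) {
    if (all(d[[outcome_col]] > 0)) {
      # near-saturated fits can emit NaN warnings from the gamma
      # likelihood; the finite-AIC guard below handles those cases
      fit_gam <- suppressWarnings(glm(f, data = d,
                                      family = Gamma(link = "log")))
      aic["gamma"] <- suppressWarnings(AIC(fit_gam))
      pick_gamma <- if (family == "gamma") TRUE else
        is.finite(aic["gamma"]) && aic["gamma"] < aic["gaussian"]
      if (pick_gamma) { fit <- fit_gam; fam <- "gamma-log" }
    } else if (family == "gamma") {
      message("fit_outcome: non-positive outcome values; gamma skipped, ",
              "keeping gaussian-identity")
    }
  }
  structure(list(outcome = outcome_col, fit = fit, family = fam,
                 aic = aic, n = nrow(d), n_dropped = sum(!cc),
                 covariates = covariates),
            class = "outcome_fit")
}

#' Estimated marginal means for the group contrast
#'
#' Predicts each group's mean on the response scale with continuous
#' covariates held at their sample means and categorical covariates
#' averaged over the observed sample distribution (population-averaged
#' marginal means; `weights = "equal"` switches to balanced weights).
#' Confidence intervals are formed on the link scale and back-transformed;
#' the p-value is the Wald test of the group contrast.
#'
#' @param fit an `outcome_fit`.
#' @param weights `"proportional"` (observed covariate distribution,
#'   default) or `"equal"`.
#' @param level confidence level.
#' @return list of class `marginal_means_result`: `means` (data frame:
#'   group, mean, lower, upper), `contrast` (group contrast with CI, a
#'   difference on the identity link or a ratio on the log link),
#'   `p_value`, `percent_difference` (first group vs second, symmetric
#'   form), `family`, `outcome`.
#' @export
marginal_means <- function(fit, weights = c("proportional", "equal"),
                           level = 0.95) {
  stopifnot(inherits(fit, "outcome_fit"))
  weights <- match.arg(weights)
  grid <- emmeans::emmeans(fit$fit, "group", weights = weights,
                           type = "response", level = level)
  s <- as.data.frame(summary(grid, level = level))
  mean_col <- intersect(c("response", "emmean"), names(s))[1]
  lcl <- intersect(c("asymp.LCL", "lower.CL"), names(s))[1]
  ucl <- intersect(c("asymp.UCL", "upper.CL"), names(s))[1]
  means <- data.frame(group = as.character(s$group),
                      mean = s[[mean_col]],
                      lower = s[[lcl]], upper = s[[ucl]])
  ct <- as.data.frame(summary(emmeans::contrast(grid, "pairwise"),
                              infer = c(TRUE, TRUE)))
  p <- ct$p.value[1]
  est_col <- intersect(c("estimate", "ratio"), names(ct))[1]
  lcl <- intersect(c("asymp.LCL", "lower.CL"), names(ct))[1]
  ucl <- intersect(c("asymp.UCL", "upper.CL"), names(ct))[1]
  contrast <- data.frame(scale = if (est_col == "ratio") "ratio" else
    "difference", estimate = ct[[est_col]][1],
    lower = ct[[lcl]][1], upper = ct[[ucl]][1])
  if (nrow(means) < 2L) stop("group contrast needs two groups")
  # undefined (NA) rather than warned here: a non-positive mean sum is
  # routine for sign-free outcomes such as the intensity gradient
  pct <- if (means$mean[1] + means$mean[2] > 0)
    symmetric_percent_difference(means$mean[1], means$mean[2]) else NA_real_
  structure(list(outcome = fit$outcome, means = means, p_value = p,
                 contrast = contrast, percent_difference = pct,
                 family = fit$family, n = fit$n),
            class = "marginal_means_result")
}

#' Symmetric percent difference between two group means
#'
#' `100 * (a - b) / ((a + b) / 2)`: the difference expressed against the
#' midpoint of the two means, so that swapping the groups only flips the
#' sign and rescaling both means leaves it unchanged.
#'
#' @param a,b group means (same units, `a + b > 0`).
#' @return percent difference.
#' @export
symmetric_percent_difference <- function(a, b) {
  if (any(a + b <= 0)) {
    warning("symmetric percent difference undefined for a + b <= 0")
    return(ifelse(a + b <= 0, NA_real_, 100 * (a - b) / ((a + b) / 2)))
  }
  100 * (a - b) / ((a + b) / 2)
}

#' Compare every outcome between groups
#'
#' Joins the participant metric table to the covariate table, fits each
#' outcome with [fit_outcome()] and summarises it with
#' [marginal_means()].
#'
#' @param metrics data frame with `id` and one column per outcome.
#' @param covariates data frame with `id`, `group` and the adjustment
#'   covariates.
#' @param outcomes outcome column names (default: every non-id metric
#'   column).
#' @param covariate_cols adjustment covariates passed to [fit_outcome()].
#' @param weights see [marginal_means()].
#' @return data frame of class `comparison_table`: one row per outcome
#'   with each group's adjusted mean and CI, p-value, chosen family and
#'   percent difference.
#' @export
compare_groups <- function(metrics, covariates,
                           outcomes = setdiff(names(metrics),
                                              c("id", "valid_days")),
                           covariate_cols = .covariate_set,
                           weights = "proportional") {
  unmatched <- setdiff(metrics$id, covariates$id)
  if (length(unmatched))
    warning("dropping ", length(unmatched),
            " metric row(s) without covariates: ",
            paste(head(unmatched, 5), collapse = ", "))
  d <- merge(metrics, covariates, by = "id")
  # reference group = first to appear in the covariate table
  if (!is.factor(d$group))
    d$group <- factor(d$group, levels = unique(covariates$group))
  rows <- lapply(outcomes, function(oc) {
    fit <- fit_outcome(d, oc, covariate_cols)
    mm <- marginal_means(fit, weights = weights)
    g <- mm$means
    data.frame(outcome = oc,
               group1 = g$group[1], mean1 = g$mean[1],
               lower1 = g$lower[1], upper1 = g$upper[1],
               group2 = g$group[2], mean2 = g$mean[2],
               lower2 = g$lower[2], upper2 = g$upper[2],
               p_value = mm$p_value, family = mm$family,
               percent_difference = mm$percent_difference,
               n = mm$n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Format a comparison table as plain text
#' @param x a `comparison_table`.
#' @param digits digits for means/CIs.
#' @return character vector of report lines (invisibly printed).
#' @export
format_comparison <- function(x, digits = 1) {
  f <- function(v) formatC(v, digits = digits, format = "f")
  lines <- c(sprintf("%-22s %-26s %-26s %8s %8s", "Outcome",
                     as.character(x$group1[1]), as.character(x$group2[1]),
                     "p", "% Diff"),
             vapply(seq_len(nrow(x)), function(i) sprintf(
               "%-22s %8s (%s, %s)   %8s (%s, %s)   %8s %8s",
               x$outcome[i], f(x$mean1[i]), f(x$lower1[i]), f(x$upper1[i]),
               f(x$mean2[i]), f(x$lower2[i]), f(x$upper2[i]),
               format.pval(x$p_value[i], digits = 3, eps = 0.001),
               f(x$percent_difference[i])), ""))
  lines
}
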