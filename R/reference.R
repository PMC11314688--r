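#' Published adjusted marginal means for the foot-ulcer contrast
#'
#' Covariate-adjusted marginal mean accelerations (mg) reported by a
#' wrist-accelerometry study of adults with type 2 diabetes with and
#' without active diabetic foot ulcers, for the MX metrics (most active
#' continuous and accumulated 5-120 min) and average acceleration. These
#' serve as worked-example inputs for the percent-difference operation and
#' the clinically-important-difference multiple; they are published group
#' summaries, not participant data.
#'
#' @return data frame: `outcome`, `mean_nondfu`, `mean_dfu` (mg), and
#'   `published_pct_diff` (the percent difference printed alongside the
#'   means, 1 d.p.).
#' @export
dfu_reference_means <- function() {
  data.frame(
    outcome = c("M5_CONT", "M10_CONT", "M30_CONT", "M60_CONT", "M120_CONT",
                "M5_ACC", "M10_ACC", "M30_ACC", "M60_ACC", "M120_ACC",
                "avg_acceleration"),
    mean_nondfu = c(81.6, 67.6, 45.2, 31.1, 19.3,
                    233.4, 190.7, 134.4, 102.4, 71.2, 21.9),
    mean_dfu = c(53.4, 44.5, 30.1, 22.8, 14.6,
                 182.5, 147.7, 101.1, 79.8, 55.0, 16.9),
    published_pct_diff = c(41.8, 41.2, 40.1, 30.8, 27.7,
                           24.5, 25.4, 28.3, 24.8, 25.5, NA))
}

#' Minimum clinically important difference in average acceleration
#'
#' The 1-mg MCID for average acceleration established for health outcomes
#' in wrist-accelerometry cohorts.
#' @return mg.
#' @export
mcid_average_acceleration <- function() 1
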