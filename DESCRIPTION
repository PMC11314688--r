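Package: wristmx
Title: 24-Hour Wrist Accelerometry Movement Profiles and Group Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processes raw wrist-worn triaxial acceleration into calibrated
    5-second ENMO (Euclidean Norm Minus One) epoch series and derives 24-hour
    movement-profile metrics: average acceleration, the intensity gradient,
    time in intensity categories, prolonged inactivity bouts, the MX metrics
    (intensity of the most active accumulated and continuous 5-120 minutes),
    and sleep-window statistics from a z-angle heuristic. Includes signal
    auto-calibration to local gravity, non-wear detection and imputation,
    wear-validity screening, covariate-adjusted two-group comparison via
    generalized linear models and estimated marginal means, and a
    deterministic synthetic-cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    emmeans,
    graphics,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
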