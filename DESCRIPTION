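Package: neonmort
Title: Age- and Cause-Specific Neonatal Mortality via the Log-Quadratic Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age- and cause-specific cumulative mortality within the
    neonatal period (0-672 hours) from quarterly cohort life tables, using an
    adapted log-quadratic model in which the all-cause neonatal mortality rate
    and its square are the covariates and a per-quarter shape parameter k,
    calibrated to the observed cause-specific neonatal mortality rate, scales a
    deviation vector estimated from training residuals. Includes the standard
    constant-daily-rate comparator, leave-one-quarter-out cross-validation with
    absolute and relative error summaries, and a synthetic cohort generator
    emulating a verbal-autopsy mortality surveillance system so the complete
    analysis runs without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
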