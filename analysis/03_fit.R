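#!/usr/bin/env Rscript
# Stage 3: fit the adapted log-quadratic model per cause.
#
# On the full set of quarterly life tables, fits, for each modelled cause and
# cumulative age, log q = a + b log(nmr) + c log(nmr)^2 by OLS and estimates
# the deviation vector v from the training residuals (first right singular
# vector, normalized to 1 at 4 weeks). Fits are serialized as JSON and the
# coefficients tabulated.
#
# Usage: Rscript analysis/03_fit.R [--tables <csv>] [--out-dir <dir>]

suppressPackageStartupMessages(library(neonmort))
args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
tables_csv <- arg_val("--tables", "results/life_tables.csv")
out_dir <- arg_val("--out-dir", "results/fits")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tables <- read_life_tables_csv(tables_csv)
message(sprintf("fitting on %d quarterly life tables, nmr %.1f-%.1f per 1000",
                length(tables),
                1000 * min(sapply(tables, `[[`, "nmr")),
                1000 * max(sapply(tables, `[[`, "nmr"))))

rows <- list()
for (cause in modelled_causes()) {
  fit <- fit_logquad(tables, cause)
  write_logquad_fit(fit, file.path(out_dir, paste0(cause, ".json")))
  rows[[cause]] <- data.frame(cause = cause, age_label = fit$ages,
                              fit$coef, v = fit$v, row.names = NULL)
  message(sprintf("%-10s b at 4 weeks = %+.2f, v profile (%s)", cause,
                  fit$coef[4, "b"],
                  paste(sprintf("%.2f", fit$v), collapse = ", ")))
}
coef_tab <- do.call(rbind, rows)
utils::write.csv(format(coef_tab, digits = 6), row.names = FALSE,
                 file.path(dirname(out_dir), "fit_coefficients.csv"))
message("wrote per-cause JSON fits under ", out_dir,
        " and fit_coefficients.csv")
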