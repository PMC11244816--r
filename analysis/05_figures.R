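#!/usr/bin/env Rscript
# Stage 5: observed versus predicted age patterns.
#
# For each modelled cause, plots the observed cumulative mortality of six
# consecutive held-out quarters against the three methods' predictions.
#
# Usage: Rscript analysis/05_figures.R [--tables <csv>] [--out-dir <dir>]

suppressPackageStartupMessages(library(neonmort))
args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
tables_csv <- arg_val("--tables", "results/life_tables.csv")
out_dir <- arg_val("--out-dir", "results/figures")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tables <- read_life_tables_csv(tables_csv)
cv <- loqo_cv(tables)
quarters <- names(tables)[7:12] # six consecutive holdouts mid-window

for (cause in modelled_causes()) {
  p <- plot_cv_quarters(cv, cause, quarters = quarters)
  path <- file.path(out_dir, paste0(cause, ".png"))
  ggplot2::ggsave(path, p, width = 8, height = 5, dpi = 150)
  message("wrote ", path)
}
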