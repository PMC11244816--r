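#!/usr/bin/env Rscript
# Stage 1: simulate a surveillance cohort.
#
# Generates the default synthetic study window — 25 quarters from Q4-2010,
# 1400 live births per quarter, all-cause NMR declining log-linearly from
# 35.3 to 27.9 per 1000 live births, age-varying cause profiles, 5% missing
# death times and 0.2% missing verbal autopsies — and writes the record-level
# cohort, the quarterly birth tallies and the generator configuration.
#
# Usage: Rscript analysis/01_simulate.R [--seed <int>] [--out-dir <dir>]

suppressPackageStartupMessages(library(neonmort))
args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
seed <- as.integer(arg_val("--seed", "20101"))
out_dir <- arg_val("--out-dir", "results/data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
coh <- generate_cohort(cfg)

write_cohort_csv(coh$records, file.path(out_dir, "cohort.csv"))
write_births_csv(coh$births, file.path(out_dir, "births.csv"))
write_synthetic_config(cfg, file.path(out_dir, "config.yaml"))

message(sprintf("simulated %d neonatal deaths among %s live births over %d quarters (seed %d)",
                nrow(coh$records), format(sum(coh$births$live_births),
                                          big.mark = ","),
                cfg$n_quarters, seed))
message(sprintf("crude NMR over the window: %.1f per 1000 live births",
                1000 * nrow(coh$records) / sum(coh$births$live_births)))
message("wrote ", out_dir, "/{cohort.csv, births.csv, config.yaml}")
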