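#!/usr/bin/env Rscript
# Stage 2: from records to quarterly life tables.
#
# Applies the analyzability filters (known death time, verbal autopsy done),
# assigns age bands, and aggregates deaths into one life table per calendar
# quarter with cumulative cause-specific probabilities and the all-cause NMR.
# Exclusion tallies are logged and mirrored in a machine-readable sidecar.
#
# Usage: Rscript analysis/02_tabulate.R [--data-dir <dir>] [--out-dir <dir>]

suppressPackageStartupMessages(library(neonmort))
args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
data_dir <- arg_val("--data-dir", "results/data")
out_dir <- arg_val("--out-dir", "results")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

records <- read_cohort_csv(file.path(data_dir, "cohort.csv"))
births <- read_births_csv(file.path(data_dir, "births.csv"))
message(sprintf("read %d death records, %d quarterly birth tallies",
                nrow(records), nrow(births)))

flt <- filter_analyzable(records)
message(sprintf("excluded %d with unknown death time, %d without verbal autopsy; %d (%.0f%%) retained",
                flt$tally["no_time"], flt$tally["no_va"], nrow(flt$records),
                100 * nrow(flt$records) / nrow(records)))

bt <- build_quarter_tables(flt$records, births)
message(sprintf("built %d quarterly life tables (%d post-neonatal, %d outside window)",
                length(bt$tables), bt$tally["post_neonatal"],
                bt$tally["out_of_range"]))

band <- assign_age_band(age_at_death_hours(flt$records$birth_dt,
                                           flt$records$death_dt)[
  quarter_of(flt$records$death_dt) %in% names(bt$tables)])
message("age-band shares among tabulated deaths: ",
        paste(sprintf("%s %.0f%%", age_scheme()$labels,
                      100 * tabulate(band, 4) / length(band)),
              collapse = ", "))

write_life_tables_csv(bt$tables, file.path(out_dir, "life_tables.csv"))
jsonlite::write_json(
  list(input_records = nrow(records),
       excluded = as.list(flt$tally), retained = nrow(flt$records),
       tabulation_excluded = as.list(bt$tally)),
  file.path(out_dir, "exclusions.json"), auto_unbox = TRUE)
message("wrote ", out_dir, "/life_tables.csv and exclusions.json")
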