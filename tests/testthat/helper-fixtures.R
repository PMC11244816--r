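# Programmatic fixtures.

utc <- function(x) as.POSIXct(x, tz = "UTC")
utc_na <- function(n = 1L) {
  as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC")
}

# Cohort reproducing the printed composition arithmetic: 1007 deaths, of
# which 48 lack a death time and 2 (disjoint) lack a verbal autopsy; the 957
# analyzable deaths fall 397/142/235/183 into the four age bands.
printed_cohort <- function() {
  band_counts <- c(397L, 142L, 235L, 183L)
  band_age_hours <- c(5L, 30L, 100L, 400L)
  n_ok <- sum(band_counts)
  births <- utc("2012-01-01 06:00") + 3600 * seq_len(n_ok + 50L)
  age <- rep(band_age_hours, band_counts)
  death_records(
    record_id = sprintf("d%04d", seq_len(n_ok + 50L)),
    birth_dt = births,
    death_dt = c(births[seq_len(n_ok)] + 3600 * age,
                 utc_na(48L),                             # unknown death time
                 births[n_ok + 49:50] + 3600 * 10),       # death known, no VA
    has_va = c(rep(TRUE, n_ok), rep(TRUE, 48L), FALSE, FALSE),
    cause = c(rep("preterm", n_ok), rep("asphyxia", 48L), NA, NA))
}

# Small quarterly life tables built directly from death-count matrices.
toy_tables <- function(nmr_values, cause_deaths, live_births = 1000L,
                       causes = cause_set()) {
  scheme <- age_scheme()
  lapply(seq_along(nmr_values), function(i) {
    deaths <- matrix(0L, 4L, length(causes),
                     dimnames = list(scheme$labels, causes))
    for (cs in names(cause_deaths)) deaths[, cs] <- cause_deaths[[cs]][i, ]
    total <- round(nmr_values[i] * live_births)
    deaths[, "other"] <- deaths[, "other"] +
      as.integer(diff(c(0, round(seq_len(4) / 4 * (total - sum(deaths))))))
    cum_q <- apply(deaths, 2, cumsum) / live_births
    quarter_life_table(sprintf("T%02d", i), live_births, deaths = deaths,
                       cum_q = cum_q)
  })
}

# Default-condition synthetic quarterly tables for a given seed.
synthetic_tables <- function(seed = 1, config = synthetic_config(seed = seed)) {
  coh <- generate_cohort(config, seed = seed)
  flt <- filter_analyzable(coh$records)
  build_quarter_tables(flt$records, coh$births, quarters = coh$quarters)$tables
}
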