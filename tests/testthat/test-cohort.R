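test_that("age at death is the floored hour difference of the date-times", {
  b <- utc("2012-01-01 00:00")
  expect_identical(age_at_death_hours(b, utc("2012-01-01 10:30")), 10L)
  expect_identical(age_at_death_hours(b, b), 0L)
  # crossing midnight twice: 2012-01-01 23:00 to 2012-01-03 01:00 is 26 h
  expect_identical(
    age_at_death_hours(utc("2012-01-01 23:00"), utc("2012-01-03 01:00")), 26L)
  expect_error(age_at_death_hours(b, b - 60), "precedes")
})

test_that("age bands are half-open with the last band closed at 672 h", {
  expect_identical(assign_age_band(c(0, 23)), c(1L, 1L))
  expect_identical(assign_age_band(c(24, 47, 48)), c(2L, 2L, 3L))
  expect_identical(assign_age_band(c(167, 168, 671, 672)), c(3L, 4L, 4L, 4L))
  expect_error(assign_age_band(673), class = "neonmort_post_neonatal")
})

test_that("analyzability filter reproduces the printed cohort composition", {
  coh <- printed_cohort()
  expect_identical(nrow(coh), 1007L)
  flt <- filter_analyzable(coh)
  expect_identical(nrow(flt$records), 957L)
  expect_identical(flt$tally, c(no_time = 48L, no_va = 2L))

  band <- assign_age_band(
    age_at_death_hours(flt$records$birth_dt, flt$records$death_dt))
  counts <- tabulate(band, 4L)
  expect_identical(counts, c(397L, 142L, 235L, 183L))
  expect_identical(round(100 * counts / sum(counts)), c(41, 15, 25, 19))
})

test_that("filter handles empty input, clean input, and double missingness", {
  empty <- printed_cohort()[0, ]
  flt <- filter_analyzable(empty)
  expect_identical(nrow(flt$records), 0L)
  expect_identical(flt$tally, c(no_time = 0L, no_va = 0L))

  clean <- filter_analyzable(printed_cohort()[1:10, ])
  expect_identical(nrow(clean$records), 10L)
  expect_identical(unname(clean$tally), c(0L, 0L))

  # a record missing both death time and VA counts once, under no_time
  both <- death_records("x", utc("2012-01-01 00:00"), utc_na(), FALSE,
                        NA_character_)
  expect_identical(filter_analyzable(both)$tally,
                   c(no_time = 1L, no_va = 0L))
})

test_that("filter tallies always account for every input record", {
  for (seed in 1:5) {
    coh <- generate_cohort(synthetic_config(n_quarters = 6, seed = seed))
    flt <- filter_analyzable(coh$records)
    expect_identical(nrow(flt$records) + sum(flt$tally), nrow(coh$records))
  }
})

test_that("quarter tables cover the study window and get the arithmetic right", {
  qs <- quarter_seq(2010, 4, 25)
  expect_identical(nrow(qs), 25L)
  expect_identical(qs$quarter_id[c(1, 25)], c("2010Q4", "2016Q4"))

  # a quarter with no deaths still yields a table of zeros
  births <- data.frame(year = 2012, quarter = 1, live_births = 1000)
  empty <- printed_cohort()[0, ]
  bt <- build_quarter_tables(empty, births)
  expect_identical(length(bt$tables), 1L)
  expect_true(all(bt$tables[[1]]$cum_q == 0))
  expect_identical(bt$tables[[1]]$nmr, 0)

  # cause-A band deaths (5,3,0,2) in 1000 births accumulate to
  # (0.005, 0.008, 0.008, 0.010)
  ages <- c(5, 30, 100, 400)
  n_per_band <- c(5, 3, 0, 2)
  b0 <- utc("2012-02-01 00:00") + 3600 * seq_len(10)
  rec <- death_records(sprintf("r%02d", 1:10), b0,
                       b0 + 3600 * rep(ages, n_per_band), TRUE, "asphyxia")
  bt <- build_quarter_tables(rec, births)
  expect_equal(unname(bt$tables[[1]]$cum_q[, "asphyxia"]),
               c(0.005, 0.008, 0.008, 0.010))
  expect_identical(bt$tables[[1]]$nmr, 0.010)

  expect_error(
    build_quarter_tables(rec, data.frame(year = 2012, quarter = 1,
                                         live_births = 0)),
    "invalid denominator")
})

test_that("post-neonatal and out-of-window deaths are tallied, not dropped silently", {
  births <- data.frame(year = 2012, quarter = 1, live_births = 1000)
  b0 <- c(rep(utc("2012-01-05 00:00"), 2), utc("2012-03-30 00:00"))
  rec <- death_records(c("a", "b", "c"), b0,
                       b0 + 3600 * c(700, 10, 100), TRUE, "preterm")
  bt <- build_quarter_tables(rec, births)
  # 700 h is post-neonatal; the 100 h death on 2012-04-03 falls outside the
  # single configured quarter
  expect_identical(bt$tally, c(post_neonatal = 1L, out_of_range = 1L))
  expect_identical(sum(bt$tables[[1]]$deaths), 1L)
})

test_that("observed life tables satisfy the envelope invariants", {
  tables <- synthetic_tables(seed = 3)
  for (tb in tables) {
    expect_true(all(apply(tb$cum_q, 2, function(q) all(diff(q) >= 0))))
    expect_true(all(tb$cum_q[4, ] <= tb$nmr))
    expect_lt(abs(sum(tb$cum_q[4, ]) - tb$nmr), 1e-12)
  }
})

test_that("cohort, births and life-table CSVs round-trip", {
  coh <- generate_cohort(synthetic_config(n_quarters = 4, seed = 7))
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh$records, p1)
  back <- read_cohort_csv(p1)
  expect_equal(back$record_id, coh$records$record_id)
  expect_equal(back$birth_dt, coh$records$birth_dt)
  expect_equal(back$death_dt, coh$records$death_dt)
  expect_equal(back$cause, coh$records$cause)

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_births_csv(coh$births, p2)
  expect_equal(read_births_csv(p2), coh$births)

  tables <- synthetic_tables(seed = 7)
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_life_tables_csv(tables, p3)
  back <- read_life_tables_csv(p3)
  for (i in seq_along(tables)) {
    expect_lt(max(abs(back[[i]]$cum_q - tables[[i]]$cum_q)), 1e-12)
    expect_lt(abs(back[[i]]$nmr - tables[[i]]$nmr), 1e-12)
    expect_equal(back[[i]]$deaths[, ], tables[[i]]$deaths[, ],
                 ignore_attr = TRUE)
  }
})

test_that("strict parsing names the offending rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,birth_datetime,death_datetime,has_va,cause",
               "a,2012-01-01T00:00,2012-01-01T05:00,1,preterm",
               "b,2012-13-01T00:00,,1,asphyxia"), p)
  expect_error(read_cohort_csv(p), "row\\(s\\) 2")

  writeLines(c("record_id,birth_datetime,death_datetime,has_va,cause",
               "a,2012-01-01T00:00,2012-01-01T05:00,1,dragonpox"), p)
  expect_error(read_cohort_csv(p), "dragonpox")
})
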