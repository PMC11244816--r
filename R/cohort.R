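#' Construct a table of neonatal death records
#'
#' One row per death captured by mortality surveillance: birth and death
#' date-times at minute resolution, a verbal-autopsy (VA) flag, and the
#' underlying cause code assigned from the VA (absent when no VA was done).
#'
#' @param record_id Character identifiers (unique).
#' @param birth_dt POSIXct birth date-times (required).
#' @param death_dt POSIXct death date-times; `NA` when the time of death is
#'   unknown and age in hours cannot be determined.
#' @param has_va Logical; whether a verbal autopsy was conducted.
#' @param cause Cause codes from `causes`, or `NA` when no VA was done.
#' @param causes Allowed cause codes, see [cause_set()].
#' @return A `data.frame` of class `death_records`.
#' @export
death_records <- function(record_id, birth_dt, death_dt, has_va, cause,
                          causes = cause_set()) {
  df <- data.frame(record_id = as.character(record_id),
                   birth_dt = birth_dt, death_dt = death_dt,
                   has_va = as.logical(has_va), cause = as.character(cause),
                   stringsAsFactors = FALSE)
  validate_death_records(df, causes)
}

validate_death_records <- function(df, causes = cause_set()) {
  stopifnot(inherits(df$birth_dt, "POSIXct"), inherits(df$death_dt, "POSIXct"))
  if (anyNA(df$birth_dt)) stop("birth_dt is required for every record")
  known <- !is.na(df$death_dt)
  if (any(df$death_dt[known] < df$birth_dt[known])) {
    bad <- df$record_id[known][df$death_dt[known] < df$birth_dt[known]]
    stop("death before birth for record(s): ", paste(bad, collapse = ", "))
  }
  has_cause <- !is.na(df$cause)
  if (any(has_cause & !df$has_va)) {
    bad <- df$record_id[has_cause & !df$has_va]
    stop("cause present without verbal autopsy for record(s): ",
         paste(bad, collapse = ", "))
  }
  unknown <- has_cause & !(df$cause %in% causes)
  if (any(unknown)) {
    stop("unknown cause code(s) in row(s) ",
         paste(which(unknown), collapse = ", "), ": ",
         paste(unique(df$cause[unknown]), collapse = ", "))
  }
  class(df) <- c("death_records", "data.frame")
  df
}

#' Apply the analyzability filters to a death-record table
#'
#' A death can enter the quarterly life tables only if its age in hours can be
#' determined (death time known) and a verbal autopsy was conducted (cause
#' ascertainable). Records failing either filter are excluded and tallied; a
#' record missing both is counted once, under the missing-death-time reason.
#'
#' @param records A [death_records()] table.
#' @return List with `records` (the retained subset) and `tally`, a named
#'   integer vector `c(no_time =, no_va =)`.
#' @examples
#' # an empty cohort passes through with an all-zero tally
#' r <- death_records(character(), as.POSIXct(character(), tz = "UTC"),
#'                    as.POSIXct(character(), tz = "UTC"), logical(),
#'                    character())
#' filter_analyzable(r)$tally
#' @export
filter_analyzable <- function(records) {
  no_time <- is.na(records$death_dt)
  no_va <- !records$has_va & !no_time # missing-time takes priority
  keep <- !no_time & records$has_va
  list(records = records[keep, , drop = FALSE],
       tally = c(no_time = sum(no_time), no_va = sum(no_va)))
}

#' Age at death in completed hours
#'
#' The difference between the death and birth date-times, floored to whole
#' hours.
#'
#' @param birth_dt,death_dt POSIXct vectors; `death_dt` must not precede
#'   `birth_dt`.
#' @return Integer vector of completed hours.
#' @examples
#' b <- as.POSIXct("2012-01-01 00:00", tz = "UTC")
#' age_at_death_hours(b, b + 10.5 * 3600) # 10
#' @export
age_at_death_hours <- function(birth_dt, death_dt) {
  secs <- as.numeric(difftime(death_dt, birth_dt, units = "secs"))
  if (any(secs < 0, na.rm = TRUE)) {
    stop("invalid record: death_dt precedes birth_dt")
  }
  as.integer(secs %/% 3600)
}

#' Construct a quarterly cohort life table
#'
#' Holds one calendar quarter's live births, the death counts by age band and
#' cause, the cumulative cause-specific probabilities of dying by each
#' cumulative age (deaths up to that age divided by live births), and the
#' all-cause neonatal mortality rate (NMR, per live birth).
#'
#' @param quarter_id Quarter identifier ("YYYYQn").
#' @param live_births Number of live births in the quarter (> 0 when death
#'   counts are present).
#' @param deaths Age-band x cause matrix of death counts, or `NULL` for
#'   model-generated tables carrying only `cum_q`.
#' @param cum_q Cumulative-age x cause matrix of cumulative probabilities.
#' @param nmr All-cause NMR; defaults to the sum of the last row of `cum_q`.
#' @param check_envelope Enforce that the cause-specific cumulative
#'   probabilities at 4 weeks sum to `nmr` (true for observed tables; model
#'   surfaces generated cause-by-cause need not satisfy it).
#' @return An object of class `quarter_life_table`.
#' @export
quarter_life_table <- function(quarter_id, live_births, deaths = NULL, cum_q,
                               nmr = sum(cum_q[nrow(cum_q), ]),
                               check_envelope = !is.null(deaths)) {
  cum_q <- as.matrix(cum_q)
  if (is.null(colnames(cum_q))) stop("cum_q needs cause names as colnames")
  if (any(cum_q < 0)) stop("cumulative probabilities must be non-negative")
  if (nmr < 0 || nmr > 1) stop("nmr must lie in [0, 1]")
  # observed tables are cumulative tallies; model surfaces need not be
  # monotone nor constrained by the all-cause envelope
  if (check_envelope) {
    if (any(apply(cum_q, 2L, function(q) any(diff(q) < -1e-12)))) {
      stop("cum_q must be non-decreasing in age for every cause")
    }
    if (abs(sum(cum_q[nrow(cum_q), ]) - nmr) > 1e-9) {
      stop("cause-specific 4-week probabilities must sum to the all-cause nmr")
    }
  }
  structure(list(quarter_id = quarter_id, live_births = live_births,
                 deaths = deaths, cum_q = cum_q, nmr = nmr),
            class = "quarter_life_table")
}

#' @export
print.quarter_life_table <- function(x, ...) {
  cat(sprintf("Quarter %s: %s live births, nmr = %.5f\n", x$quarter_id,
              format(x$live_births, big.mark = ","), x$nmr))
  print(round(x$cum_q, 5))
  invisible(x)
}

#' Aggregate filtered death records into quarterly life tables
#'
#' Deaths are assigned to the calendar quarter containing the date of death;
#' the denominator of each quarter is the live births whose birth falls in
#' that quarter (supplied as a tally). Quarters with no deaths are still
#' emitted. Post-neonatal deaths (age beyond 672 completed hours) and deaths
#' falling outside the configured quarter range are excluded and tallied,
#' never silently dropped. Retained records with a verbal autopsy but a cause
#' outside `causes` count under the catch-all `"other"`.
#'
#' @param records Filtered [death_records()] (see [filter_analyzable()]).
#' @param births Data frame with columns `year`, `quarter`, `live_births`.
#' @param scheme An [age_scheme()].
#' @param causes Cause codes, see [cause_set()].
#' @param quarters Optional `quarter_seq()`-style frame restricting the study
#'   window; defaults to all quarters present in `births`.
#' @return List with `tables` (one [quarter_life_table()] per quarter, in
#'   order) and `tally` (`post_neonatal`, `out_of_range` exclusion counts).
#' @export
build_quarter_tables <- function(records, births, scheme = age_scheme(),
                                 causes = cause_set(), quarters = NULL) {
  if (anyNA(records$death_dt)) {
    stop("records must be filtered first: unknown death times present")
  }
  if (is.null(quarters)) {
    qid <- quarter_id(births$year, births$quarter)
    quarters <- data.frame(year = births$year, quarter = births$quarter,
                           quarter_id = qid, stringsAsFactors = FALSE)
    quarters <- quarters[order(quarters$year, quarters$quarter), ]
  }
  births_by_q <- stats::setNames(births$live_births,
                                 quarter_id(births$year, births$quarter))
  missing_b <- setdiff(quarters$quarter_id, names(births_by_q))
  if (length(missing_b)) {
    stop("no birth tally for quarter(s): ", paste(missing_b, collapse = ", "))
  }
  if (any(births_by_q[quarters$quarter_id] <= 0)) {
    stop("invalid denominator: quarter(s) with zero live births: ",
         paste(quarters$quarter_id[births_by_q[quarters$quarter_id] <= 0],
               collapse = ", "))
  }

  age <- age_at_death_hours(records$birth_dt, records$death_dt)
  post <- age > scheme$bounds[length(scheme$bounds)]
  dq <- quarter_of(records$death_dt)
  oor <- !post & !(dq %in% quarters$quarter_id)
  keep <- !post & !oor
  tally <- c(post_neonatal = sum(post), out_of_range = sum(oor))

  band <- integer(nrow(records))
  band[keep] <- assign_age_band(age[keep], scheme)
  cause <- records$cause
  cause[is.na(cause) | !(cause %in% causes)] <- "other"

  n_band <- length(scheme$bounds)
  tables <- lapply(seq_len(nrow(quarters)), function(i) {
    qid <- quarters$quarter_id[i]
    lb <- unname(births_by_q[[qid]])
    sel <- keep & dq == qid
    deaths <- table(factor(band[sel], levels = seq_len(n_band)),
                    factor(cause[sel], levels = causes))
    deaths <- matrix(as.integer(deaths), nrow = n_band,
                     dimnames = list(scheme$labels, causes))
    cum_q <- apply(deaths, 2L, cumsum) / lb
    rownames(cum_q) <- scheme$labels
    quarter_life_table(qid, lb, deaths = deaths, cum_q = cum_q)
  })
  names(tables) <- quarters$quarter_id
  list(tables = tables, tally = tally)
}

# quarters x cumulative-ages matrix of one cause's cumulative probabilities
cumq_matrix <- function(tables, cause) {
  t(vapply(tables, function(tb) tb$cum_q[, cause],
           numeric(nrow(tables[[1L]]$cum_q))))
}

nmr_of <- function(tables) vapply(tables, `[[`, numeric(1L), "nmr")
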