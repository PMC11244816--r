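# Delimited-text interfaces. All parsing is strict: malformed date-times or
# unknown cause codes are errors naming the offending row.

#' Read and write record-level cohort CSV files
#'
#' Columns: `record_id`, `birth_datetime` (ISO-8601, minute resolution),
#' `death_datetime` (ISO-8601 or empty when unknown), `has_va` (0/1),
#' `cause` (code or empty).
#'
#' @param path File path.
#' @param causes Allowed cause codes, see [cause_set()].
#' @return `read_cohort_csv()` returns a [death_records()] table;
#'   writers return `path` invisibly.
#' @export
read_cohort_csv <- function(path, causes = cause_set()) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("record_id", "birth_datetime", "death_datetime", "has_va", "cause")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$has_va %in% c("0", "1"))) {
    stop("has_va must be 0/1; offending row(s): ",
         paste(which(!df$has_va %in% c("0", "1")), collapse = ", "))
  }
  cause <- df$cause
  cause[!nzchar(cause)] <- NA_character_
  bad <- !is.na(cause) & !(cause %in% causes)
  if (any(bad)) {
    stop("unknown cause code(s) in row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(cause[bad]), collapse = ", "))
  }
  validate_death_records(
    data.frame(record_id = df$record_id,
               birth_dt = parse_datetime_strict(df$birth_datetime,
                                                "birth_datetime"),
               death_dt = parse_datetime_strict(df$death_datetime,
                                                "death_datetime"),
               has_va = df$has_va == "1", cause = cause,
               stringsAsFactors = FALSE),
    causes)
}

#' @rdname read_cohort_csv
#' @param records A [death_records()] table.
#' @export
write_cohort_csv <- function(records, path) {
  out <- data.frame(record_id = records$record_id,
                    birth_datetime = format_datetime(records$birth_dt),
                    death_datetime = format_datetime(records$death_dt),
                    has_va = as.integer(records$has_va),
                    cause = ifelse(is.na(records$cause), "", records$cause),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write quarterly live-birth tallies
#'
#' Columns: `year`, `quarter` (1-4), `live_births`.
#'
#' @param path File path.
#' @return `read_births_csv()` returns a data frame; the writer returns
#'   `path` invisibly.
#' @export
read_births_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("year", "quarter", "live_births")
  if (!all(need %in% names(df))) {
    stop("births CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$quarter %in% 1:4)) {
    stop("quarter must be in 1..4; offending row(s): ",
         paste(which(!df$quarter %in% 1:4), collapse = ", "))
  }
  df[need]
}

#' @rdname read_births_csv
#' @param births Data frame with columns `year`, `quarter`, `live_births`.
#' @export
write_births_csv <- function(births, path) {
  utils::write.csv(births[c("year", "quarter", "live_births")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write quarterly life tables as long-format CSV
#'
#' One row per quarter x age band x cause with the band death count and the
#' cumulative probability by that age, plus the per-quarter `live_births`
#' and all-cause `nmr` repeated on each row. Values round-trip to full
#' double precision.
#'
#' @param tables List of [quarter_life_table()]s.
#' @param path File path.
#' @return `read_life_tables_csv()` returns the list of tables; the writer
#'   returns `path` invisibly.
#' @export
write_life_tables_csv <- function(tables, path) {
  rows <- lapply(tables, function(tb) {
    grid <- expand.grid(age_label = rownames(tb$cum_q),
                        cause = colnames(tb$cum_q),
                        stringsAsFactors = FALSE)
    data.frame(quarter = tb$quarter_id, grid,
               deaths = if (is.null(tb$deaths)) NA_integer_
                        else as.vector(tb$deaths),
               cum_q = as.vector(tb$cum_q),
               live_births = tb$live_births, nmr = tb$nmr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$cum_q <- sprintf("%.17g", out$cum_q)
  out$nmr <- sprintf("%.17g", out$nmr)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_life_tables_csv
#' @export
read_life_tables_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("quarter", "age_label", "cause", "deaths", "cum_q",
            "live_births", "nmr")
  if (!all(need %in% names(df))) {
    stop("life-table CSV must have columns: ", paste(need, collapse = ", "))
  }
  ages <- unique(df$age_label)
  causes <- unique(df$cause)
  tables <- lapply(split(df, factor(df$quarter, levels = unique(df$quarter))),
                   function(d) {
    shape <- function(col) {
      m <- matrix(NA_real_, length(ages), length(causes),
                  dimnames = list(ages, causes))
      m[cbind(match(d$age_label, ages), match(d$cause, causes))] <- d[[col]]
      m
    }
    quarter_life_table(d$quarter[1L], d$live_births[1L],
                       deaths = shape("deaths"), cum_q = shape("cum_q"),
                       nmr = d$nmr[1L])
  })
  names(tables) <- unique(df$quarter)
  tables
}

#' Read and write a generator configuration (YAML or JSON)
#'
#' The format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @return `read_synthetic_config()` returns a [synthetic_config()]; the
#'   writer returns `path` invisibly.
#' @export
read_synthetic_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  profile <- matrix(unlist(obj$cause_age_profile$values),
                    nrow = length(obj$cause_age_profile$causes),
                    dimnames = list(obj$cause_age_profile$causes,
                                    obj$cause_age_profile$bands))
  synthetic_config(n_quarters = obj$n_quarters, start_year = obj$start_year,
                   start_quarter = obj$start_quarter,
                   births_per_quarter = obj$births_per_quarter,
                   nmr_start = obj$nmr_start, nmr_end = obj$nmr_end,
                   age_band_weights = obj$age_band_weights,
                   cause_age_profile = profile,
                   p_missing_time = obj$p_missing_time,
                   p_missing_va = obj$p_missing_va, seed = obj$seed)
}

#' @rdname read_synthetic_config
#' @param config A [synthetic_config()].
#' @export
write_synthetic_config <- function(config, path) {
  obj <- config[setdiff(names(config), "cause_age_profile")]
  obj$cause_age_profile <- list(
    causes = rownames(config$cause_age_profile),
    bands = colnames(config$cause_age_profile),
    values = apply(config$cause_age_profile, 2L, identity, simplify = FALSE))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
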