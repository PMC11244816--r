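# Calendar-quarter helpers. Quarters are identified as "YYYYQn"; all
# date-times are POSIXct in UTC at minute resolution.

quarter_id <- function(year, quarter) sprintf("%04dQ%d", year, quarter)

#' Sequence of calendar quarters
#'
#' @param start_year,start_quarter First quarter of the study window.
#' @param n Number of consecutive quarters.
#' @return Data frame with columns `year`, `quarter`, `quarter_id`, and the
#'   UTC `start` and `end` (exclusive) of each quarter.
#' @examples
#' quarter_seq(2010, 4, 25) # Q4-2010 through Q4-2016
#' @export
quarter_seq <- function(start_year, start_quarter, n) {
  if (!start_quarter %in% 1:4) stop("start_quarter must be in 1..4")
  idx <- (start_year * 4L + (start_quarter - 1L)) + seq_len(n) - 1L
  year <- idx %/% 4L
  quarter <- idx %% 4L + 1L
  start <- as.POSIXct(sprintf("%04d-%02d-01 00:00:00", year,
                              (quarter - 1L) * 3L + 1L), tz = "UTC")
  nxt <- idx + 1L
  end <- as.POSIXct(sprintf("%04d-%02d-01 00:00:00", nxt %/% 4L,
                            (nxt %% 4L) * 3L + 1L), tz = "UTC")
  data.frame(year = year, quarter = quarter,
             quarter_id = quarter_id(year, quarter),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Calendar quarter containing a date-time
#'
#' @param dt POSIXct vector.
#' @return Character vector of quarter ids ("YYYYQn").
#' @export
quarter_of <- function(dt) {
  lt <- as.POSIXlt(dt, tz = "UTC")
  quarter_id(lt$year + 1900L, lt$mon %/% 3L + 1L)
}

# Strict ISO-8601 minute/second resolution parser; NA only for empty strings.
parse_datetime_strict <- function(x, what = "datetime") {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  nonempty <- !is.na(x) & nzchar(x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}(:\\d{2})?$", x[nonempty])
  xs <- sub("T", " ", x[nonempty])
  parsed <- as.POSIXct(strptime(xs, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  retry <- is.na(parsed)
  parsed[retry] <- as.POSIXct(strptime(xs[retry], "%Y-%m-%d %H:%M",
                                       tz = "UTC"))
  bad <- !ok | is.na(parsed)
  if (any(bad)) {
    rows <- which(nonempty)[bad]
    stop(sprintf("malformed %s in row(s) %s: %s", what,
                 paste(rows, collapse = ", "),
                 paste(unique(x[rows]), collapse = ", ")))
  }
  out[nonempty] <- parsed
  out
}

format_datetime <- function(dt) {
  out <- format(dt, "%Y-%m-%dT%H:%M", tz = "UTC")
  out[is.na(dt)] <- ""
  out
}
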