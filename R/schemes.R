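#' Cumulative age-group scheme for the neonatal period
#'
#' The neonatal period is divided into contiguous age bands defined by
#' cumulative upper bounds in completed hours. The default scheme uses four
#' bands: first day, second day, remainder of the first week, and weeks two to
#' four. Bands are half-open `[lower, upper)` except the last, which is closed
#' at 672 hours (28 days): a death at exactly 672 completed hours is neonatal.
#'
#' @param bounds Integer vector of strictly increasing cumulative upper bounds
#'   in completed hours. The last bound must be 672 (28 days), the end of the
#'   neonatal period.
#' @param labels Character labels for the cumulative ages, one per bound.
#'
#' @return An object of class `age_scheme` with elements `bounds`, `lower`
#'   (band lower bounds) and `labels`.
#' @examples
#' sch <- age_scheme()
#' sch$labels
#' @export
age_scheme <- function(bounds = c(24L, 48L, 168L, 672L),
                       labels = c("0-23h", "0-47h", "0h-6 days", "0h-4weeks")) {
  bounds <- as.integer(bounds)
  if (length(bounds) < 2L) stop("age scheme needs at least two bounds")
  if (any(diff(bounds) <= 0L) || bounds[1L] <= 0L) {
    stop("age scheme bounds must be strictly increasing and positive")
  }
  if (bounds[length(bounds)] != 672L) {
    stop("last age bound must be 672 hours (end of the neonatal period)")
  }
  if (length(labels) != length(bounds)) {
    stop("need one label per bound")
  }
  structure(
    list(bounds = bounds, lower = c(0L, bounds[-length(bounds)]),
         labels = as.character(labels)),
    class = "age_scheme"
  )
}

#' @export
print.age_scheme <- function(x, ...) {
  cat("Neonatal age-group scheme (", length(x$bounds), " bands)\n", sep = "")
  for (i in seq_along(x$bounds)) {
    close_br <- if (i == length(x$bounds)) "]" else ")"
    cat(sprintf("  %-10s [%d, %d%s hours\n", x$labels[i], x$lower[i],
                x$bounds[i], close_br))
  }
  invisible(x)
}

#' Cause-of-death code sets
#'
#' `cause_set()` returns the ordered cause codes used throughout the package;
#' `modelled_causes()` returns the subset that receives a log-quadratic fit.
#' The default set holds the five most common causes of neonatal death in a
#' high-mortality verbal-autopsy setting plus a catch-all `"other"` which
#' contributes to the all-cause neonatal mortality rate but is never modelled.
#'
#' @param causes Character vector of unique cause codes; must contain
#'   `"other"`.
#' @return Character vector of cause codes.
#' @examples
#' cause_set()
#' modelled_causes()
#' @export
cause_set <- function(causes = c("preterm", "asphyxia", "sepsis",
                                 "pneumonia", "congenital", "other")) {
  causes <- as.character(causes)
  if (anyDuplicated(causes)) stop("cause codes must be unique")
  if (!"other" %in% causes) stop("cause set must contain the catch-all 'other'")
  causes
}

#' @rdname cause_set
#' @export
modelled_causes <- function(causes = cause_set()) {
  setdiff(causes, "other")
}

#' Assign a death to an age band
#'
#' @param age_hours Age at death in completed hours (non-negative integer).
#' @param scheme An [age_scheme()].
#' @return Integer band index (1-based).
#'
#' Ages beyond the last bound are post-neonatal and signal an error of class
#' `neonmort_post_neonatal`; callers tabulating cohorts catch this and tally
#' the record instead of dropping it silently.
#' @examples
#' assign_age_band(0)
#' assign_age_band(24)
#' assign_age_band(672)
#' @export
assign_age_band <- function(age_hours, scheme = age_scheme()) {
  if (any(age_hours < 0)) stop("age_hours must be non-negative")
  n <- length(scheme$bounds)
  last <- scheme$bounds[n]
  if (any(age_hours > last)) {
    stop(errorCondition(
      sprintf("age %s h is beyond the neonatal period (> %d h)",
              paste(age_hours[age_hours > last], collapse = ", "), last),
      class = c("neonmort_post_neonatal", "error", "condition")
    ))
  }
  # half-open bands [lower, upper); the last band is closed at `last`
  band <- findInterval(age_hours, c(0L, scheme$bounds))
  band[age_hours == last] <- n
  as.integer(band)
}
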