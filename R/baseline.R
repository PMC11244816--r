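#' Standard constant-daily-rate prediction
#'
#' The comparator used in practice for health-system planning: assume a
#' constant daily cause-specific mortality rate across the whole neonatal
#' period, i.e. allocate the 28-day cumulative risk linearly by elapsed time.
#' The cumulative prediction at an age bound of `h` hours is
#' `cause_nmr * h / 672`, so the prediction at 4 weeks always equals the
#' supplied cause-specific rate exactly.
#'
#' @param cause_nmr Cause-specific neonatal mortality rate (in `[0, 1]`).
#' @param scheme An [age_scheme()].
#' @return Named numeric vector of cumulative predictions, one per cumulative
#'   age; monotone non-decreasing and linear in `cause_nmr`.
#' @examples
#' standard_predict(0.028) # 1/28, 2/28, 7/28 and all of 0.028
#' @export
standard_predict <- function(cause_nmr, scheme = age_scheme()) {
  if (cause_nmr < 0 || cause_nmr > 1) stop("cause_nmr must lie in [0, 1]")
  last <- scheme$bounds[length(scheme$bounds)]
  # bounds/last first so the 4-week entry is cause_nmr * 1 exactly
  stats::setNames(cause_nmr * (scheme$bounds / last), scheme$labels)
}
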