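#' Plot observed versus predicted age patterns for held-out quarters
#'
#' For one cause, draws the observed cumulative mortality by cumulative age
#' in each held-out quarter together with the three methods' predictions
#' (log-quadratic with `k = 0`, with calibrated `k`, and the constant
#' daily-rate baseline), faceted by quarter.
#'
#' @param cv A [loqo_cv()] result.
#' @param cause Cause code to display.
#' @param quarters Optional character vector of quarter ids (e.g. six
#'   consecutive quarters); defaults to all holdouts.
#' @return A ggplot object.
#' @export
plot_cv_quarters <- function(cv, cause, quarters = NULL) {
  d <- cv$details[cv$details$cause == cause, ]
  if (!nrow(d)) stop("no detail records for cause ", cause)
  if (!is.null(quarters)) d <- d[d$quarter %in% quarters, ]
  ages <- unique(d$age_label)
  d$age <- match(d$age_label, ages)
  method_labels <- c(k0 = "log-quadratic, k = 0",
                     best_k = "log-quadratic, best k",
                     standard = "constant daily rate")
  d$method <- factor(method_labels[d$method], levels = unname(method_labels))
  obs <- unique(d[c("quarter", "age", "observed")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted,
                                    colour = .data$method)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$observed),
                        shape = 1) +
    ggplot2::facet_wrap(~quarter) +
    ggplot2::scale_x_continuous(breaks = seq_along(ages), labels = ages) +
    ggplot2::labs(x = "cumulative age", y = "cumulative probability of death",
                  colour = NULL,
                  title = sprintf("Observed vs predicted mortality: %s",
                                  cause)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = "bottom")
}
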