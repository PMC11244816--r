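#' Leave-one-quarter-out cross-validation of the three estimation methods
#'
#' Holds out each quarterly life table in turn, fits the log-quadratic model
#' per cause on the remaining quarters, and predicts the holdout's cumulative
#' cause-specific mortality at every cumulative age by three methods:
#'
#' * `k0` — log-quadratic prediction with shape parameter `k = 0`;
#' * `best_k` — log-quadratic prediction with `k` calibrated to the
#'   holdout's observed cause-specific neonatal mortality rate;
#' * `standard` — the constant-daily-rate allocation of that same observed
#'   cause-specific rate.
#'
#' The holdout's observed all-cause nmr (the model covariate) and its
#' observed cause-specific rate (for calibration and the baseline) are
#' treated as known at prediction time: the exercise validates the estimated
#' age *pattern* given the level. By construction the `best_k` and
#' `standard` errors at the last cumulative age are exactly zero whenever the
#' observed cause-specific rate is positive (a zero-observed holdout enters
#' `best_k` through the zero-cell offset, contributing an error of at most
#' `offset` at that age).
#'
#' Absolute error is `|predicted - observed|`, averaged over holdouts.
#' Relative error averages `|predicted - observed| / observed` over holdouts
#' with a positive observed value, and is reported as `NA` for causes listed
#' in `rare_causes`, whose observed quarterly rates are often zero.
#'
#' @param tables List of [quarter_life_table()]s (>= 5; 25 in a full study
#'   window).
#' @param causes Causes to cross-validate (default the five modelled causes).
#' @param scheme An [age_scheme()].
#' @param offset Zero-cell offset used in fitting and calibration.
#' @param rare_causes Causes whose relative error is suppressed.
#' @return An object of class `loqo_cv`: list with `summary` (one row per
#'   cause x cumulative age x method, columns `abs_err` and `rel_err`) and
#'   `details` (one row per holdout x cause x age x method with `observed`
#'   and `predicted`).
#' @export
loqo_cv <- function(tables, causes = modelled_causes(), scheme = age_scheme(),
                    offset = 1e-5,
                    rare_causes = c("sepsis", "pneumonia", "congenital")) {
  n <- length(tables)
  if (n < 5L) stop("need at least 5 quarters for leave-one-quarter-out CV")
  ages <- rownames(tables[[1L]]$cum_q)
  n_age <- length(ages)
  methods <- c("k0", "best_k", "standard")

  rows <- vector("list", n * length(causes) * length(methods))
  r <- 0L
  for (t in seq_len(n)) {
    train <- tables[-t]
    holdout <- tables[[t]]
    qid <- holdout$quarter_id
    for (cause in causes) {
      fit <- tryCatch(
        fit_logquad(train, cause, offset),
        error = function(e) {
          stop(sprintf("fold holding out quarter %s, cause %s: %s",
                       qid, cause, conditionMessage(e)), call. = FALSE)
        })
      obs <- holdout$cum_q[, cause]
      cause_nmr <- obs[n_age]
      pred <- list(
        k0 = predict(fit, holdout$nmr, k = 0),
        best_k = predict(fit, holdout$nmr,
                         k = calibrate_k(fit, holdout$nmr, cause_nmr)),
        standard = standard_predict(cause_nmr, scheme)
      )
      for (m in methods) {
        r <- r + 1L
        rows[[r]] <- data.frame(
          quarter = qid, cause = cause, age_label = ages, method = m,
          observed = unname(obs), predicted = unname(pred[[m]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  details <- do.call(rbind, rows)
  rownames(details) <- NULL

  grid <- expand.grid(method = methods, age_label = ages, cause = causes,
                      stringsAsFactors = FALSE)[, 3:1]
  summ <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    d <- details[details$cause == grid$cause[i] &
                   details$age_label == grid$age_label[i] &
                   details$method == grid$method[i], ]
    err <- abs(d$predicted - d$observed)
    pos <- d$observed > 0
    rel <- if (grid$cause[i] %in% rare_causes || !any(pos)) {
      NA_real_
    } else {
      mean(err[pos] / d$observed[pos])
    }
    data.frame(cause = grid$cause[i], age_label = grid$age_label[i],
               method = grid$method[i], abs_err = mean(err), rel_err = rel,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  structure(list(summary = summ, details = details, n_holdouts = n,
                 offset = offset, rare_causes = rare_causes),
            class = "loqo_cv")
}

#' @export
print.loqo_cv <- function(x, ...) {
  cat(sprintf("Leave-one-quarter-out cross-validation (%d holdouts)\n\n",
              x$n_holdouts))
  print(cv_table(x), row.names = FALSE)
  invisible(x)
}

#' Arrange a cross-validation summary as a wide table
#'
#' One row per cause and cumulative age, with average absolute and relative
#' error columns for the three methods, errors rounded to 5 decimal places
#' (relative errors to 3) as conventionally reported.
#'
#' @param cv A [loqo_cv()] result.
#' @return Data frame with columns `cause`, `age_label`, `abs_err_k0`,
#'   `abs_err_bestk`, `abs_err_standard`, `rel_err_k0`, `rel_err_bestk`,
#'   `rel_err_standard`.
#' @export
cv_table <- function(cv) {
  s <- cv$summary
  pick <- function(m, col) {
    v <- s[s$method == m, c("cause", "age_label", col)]
    names(v)[3L] <- paste0(col, "_", sub("_", "", m))
    v
  }
  out <- Reduce(function(a, b) merge(a, b, sort = FALSE),
                list(pick("k0", "abs_err"), pick("best_k", "abs_err"),
                     pick("standard", "abs_err"), pick("k0", "rel_err"),
                     pick("best_k", "rel_err"), pick("standard", "rel_err")))
  out[grep("^abs", names(out))] <- round(out[grep("^abs", names(out))], 5)
  out[grep("^rel", names(out))] <- round(out[grep("^rel", names(out))], 3)
  out
}

#' Write cross-validation outputs as CSV
#'
#' `write_cv_csv()` writes the wide summary table (empty cells for undefined
#' relative errors); `write_cv_details_csv()` writes the per-holdout detail
#' records at full precision.
#'
#' @param cv A [loqo_cv()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cv_csv <- function(cv, path) {
  tab <- cv_table(cv)
  fmt <- function(x, digits) ifelse(is.na(x), "",
                                    formatC(x, format = "f", digits = digits))
  for (nm in grep("^abs", names(tab), value = TRUE)) tab[[nm]] <- fmt(tab[[nm]], 5)
  for (nm in grep("^rel", names(tab), value = TRUE)) tab[[nm]] <- fmt(tab[[nm]], 3)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cv_csv
#' @export
write_cv_details_csv <- function(cv, path) {
  utils::write.csv(format(cv$details, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
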