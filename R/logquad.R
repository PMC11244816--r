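#' Fit the quadratic stage of the adapted log-quadratic model
#'
#' For one cause, regresses the log cumulative probability of dying by each
#' cumulative age on `z = log(nmr)` and `z^2` across training quarters by
#' ordinary least squares, where `nmr` is the quarter's all-cause neonatal
#' mortality rate. Cumulative-probability cells equal to zero are replaced by
#' a small offset (default 1e-5) before taking logs; the rule is applied
#' uniformly to every cause, though in practice only rare causes have zeros.
#' The quarters-by-ages residual matrix is retained for deviation-vector
#' estimation.
#'
#' @param tables List of [quarter_life_table()]s (at least 4, with at least 3
#'   distinct nmr values so the quadratic is identifiable; all nmr > 0).
#' @param cause Cause code present in the tables.
#' @param offset Probability substituted for zero cells before logs.
#' @return An object of class `logquad_fit` with the per-age coefficient
#'   matrix `coef` (columns `a`, `b`, `c`), the residual matrix, the age
#'   labels and training quarter ids, and `v = NULL` until
#'   [estimate_deviation_vector()] is applied (see [fit_logquad()]).
#' @seealso [predict.logquad_fit()], [calibrate_k()]
#' @export
fit_quadratic <- function(tables, cause, offset = 1e-5) {
  nmr <- nmr_of(tables)
  if (length(tables) < 4L) stop("need at least 4 training quarters")
  if (any(nmr <= 0)) stop("all-cause nmr must be positive in every quarter")
  z <- log(nmr)
  if (length(unique(z)) < 3L) {
    stop("singular design: fewer than 3 distinct nmr values among ",
         length(tables), " quarters")
  }
  q <- cumq_matrix(tables, cause)
  q[q == 0] <- offset
  y <- log(q)
  x <- cbind(1, z, z^2)
  fit <- stats::lm.fit(x, y)
  if (fit$rank < 3L) stop("singular design in quadratic fit")
  coefs <- t(fit$coefficients)
  colnames(coefs) <- c("a", "b", "c")
  rownames(coefs) <- rownames(tables[[1L]]$cum_q)
  resid <- fit$residuals
  rownames(resid) <- unname(vapply(tables, `[[`, character(1L), "quarter_id"))
  colnames(resid) <- rownames(coefs)
  structure(list(cause = cause, ages = rownames(coefs), coef = coefs,
                 v = NULL, residuals = resid, offset = offset,
                 quarters = rownames(resid)),
            class = "logquad_fit")
}

#' Estimate the deviation vector from a residual matrix
#'
#' The deviation vector `v` gives the age profile of the systematic departure
#' of individual quarters from the quadratic surface; a per-quarter scalar
#' `k` scales it. It is taken as the first right singular vector of the
#' quarters-by-ages residual matrix, sign-fixed so its last entry is positive
#' and rescaled so the entry at the last cumulative age equals 1 exactly.
#' With that normalization the shape parameter is available in closed form
#' (see [calibrate_k()]) and the calibrated model reproduces the observed
#' cause-specific neonatal mortality rate exactly at 4 weeks.
#'
#' @param residuals Quarters x cumulative-ages residual matrix (>= 2 rows).
#' @return Numeric deviation vector with last entry 1.
#'
#' Signals `neonmort_no_deviation_signal` when the residual matrix is
#' numerically zero (largest singular value below 1e-12) and
#' `neonmort_degenerate_deviation` when the raw last entry is too small to
#' normalize (`k` would be unidentifiable).
#' @export
estimate_deviation_vector <- function(residuals) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 2L) stop("need residuals from at least 2 quarters")
  s <- svd(residuals)
  if (s$d[1L] < 1e-12) {
    stop(errorCondition(
      "residual matrix is numerically zero: no deviation signal",
      class = c("neonmort_no_deviation_signal", "error", "condition")))
  }
  v <- s$v[, 1L]
  last <- length(v)
  if (abs(v[last]) < 1e-8) {
    stop(errorCondition(
      "deviation vector vanishes at the last cumulative age; k unidentifiable",
      class = c("neonmort_degenerate_deviation", "error", "condition")))
  }
  if (v[last] < 0) v <- -v
  v <- v / v[last]
  names(v) <- colnames(residuals)
  v
}

#' Fit the full log-quadratic model (quadratic stage plus deviation vector)
#'
#' Convenience wrapper: [fit_quadratic()] followed by
#' [estimate_deviation_vector()] on the training residuals.
#'
#' @inheritParams fit_quadratic
#' @return A `logquad_fit` carrying the deviation vector `v`.
#' @export
fit_logquad <- function(tables, cause, offset = 1e-5) {
  fit <- fit_quadratic(tables, cause, offset)
  fit$v <- estimate_deviation_vector(fit$residuals)
  fit
}

#' @export
print.logquad_fit <- function(x, ...) {
  cat(sprintf("Log-quadratic fit for cause '%s' (%d training quarters)\n",
              x$cause, length(x$quarters)))
  tab <- cbind(x$coef, v = if (is.null(x$v)) NA_real_ else x$v)
  print(round(tab, 4))
  invisible(x)
}

#' Predict cumulative age- and cause-specific mortality
#'
#' Evaluates `exp(a_x + b_x z + c_x z^2 + v_x k)` with `z = log(nmr)` at each
#' cumulative age `x`. With `k = 0` the prediction is the typical age pattern
#' at that all-cause mortality level and does not involve `v`; a nonzero `k`
#' shifts the pattern along the deviation vector. Predictions are strictly
#' positive but are not forced to be monotone in age: the model's raw output
#' is reported.
#'
#' @param object A `logquad_fit`.
#' @param nmr All-cause neonatal mortality rate (per live birth, > 0).
#' @param k Shape parameter; the fit must carry `v` when `k != 0`.
#' @param ... Unused.
#' @return Named numeric vector of predicted cumulative probabilities, one
#'   per cumulative age.
#' @export
predict.logquad_fit <- function(object, nmr, k = 0, ...) {
  if (nmr <= 0) stop("nmr must be positive")
  z <- log(nmr)
  eta <- object$coef[, "a"] + object$coef[, "b"] * z + object$coef[, "c"] * z^2
  if (k != 0) {
    if (is.null(object$v)) stop("fit carries no deviation vector; cannot use k != 0")
    eta <- eta + object$v * k
  }
  stats::setNames(exp(eta), object$ages)
}

#' Calibrate the shape parameter k to the cause-specific mortality rate
#'
#' With the deviation vector normalized to 1 at the last cumulative age, only
#' that age constrains `k`, so it is available in closed form:
#' `k = log(cause_nmr) - (a + b z + c z^2)` evaluated at 4 weeks. The
#' calibrated prediction then reproduces `cause_nmr` exactly at the last age.
#' A `cause_nmr` of zero is replaced by the zero-cell offset before the log,
#' the same rule used in fitting.
#'
#' @param fit A `logquad_fit` carrying `v` (with `v[last] = 1`).
#' @param nmr All-cause neonatal mortality rate of the target quarter (> 0).
#' @param cause_nmr Observed cause-specific neonatal mortality rate (>= 0).
#' @param offset Probability substituted when `cause_nmr` is zero.
#' @return The shape parameter `k` (finite scalar).
#' @examples
#' # doubling the cause-specific rate relative to the k = 0 prediction
#' # shifts k by log(2), since v[last] = 1
#' @export
calibrate_k <- function(fit, nmr, cause_nmr, offset = fit$offset) {
  if (is.null(fit$v)) stop("fit carries no deviation vector; run fit_logquad()")
  if (nmr <= 0) stop("nmr must be positive")
  if (cause_nmr < 0) stop("cause_nmr must be non-negative")
  if (cause_nmr == 0) cause_nmr <- offset
  z <- log(nmr)
  last <- nrow(fit$coef)
  eta_last <- fit$coef[last, "a"] + fit$coef[last, "b"] * z +
    fit$coef[last, "c"] * z^2
  unname(log(cause_nmr) - eta_last)
}

#' Serialize / restore a log-quadratic fit as JSON
#'
#' Round-trip stable: coefficients, deviation vector, offset, age labels and
#' training quarter ids are written at full double precision.
#'
#' @param fit A `logquad_fit`.
#' @param path File path.
#' @return `read_logquad_fit()` returns the restored `logquad_fit`;
#'   `write_logquad_fit()` returns `path` invisibly.
#' @export
write_logquad_fit <- function(fit, path) {
  obj <- list(cause = fit$cause, ages = fit$ages,
              a = unname(fit$coef[, "a"]), b = unname(fit$coef[, "b"]),
              c = unname(fit$coef[, "c"]),
              v = if (is.null(fit$v)) NULL else unname(fit$v),
              offset = fit$offset, quarters = fit$quarters)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_logquad_fit
#' @export
read_logquad_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- cbind(a = obj$a, b = obj$b, c = obj$c)
  rownames(coefs) <- obj$ages
  v <- obj$v
  if (!is.null(v)) names(v) <- obj$ages
  structure(list(cause = obj$cause, ages = obj$ages, coef = coefs, v = v,
                 residuals = NULL, offset = obj$offset,
                 quarters = obj$quarters),
            class = "logquad_fit")
}
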