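true_coef <- cbind(a = c(-1.8, -1.5, -1.2, -0.9),
                   b = c(1.2, 1.1, 1.0, 1.0),
                   c = c(0.05, 0.03, 0.02, 0.0))
true_v <- c(0.3, 0.5, 0.8, 1.0)

test_that("noise-free model surfaces are recovered to numerical precision", {
  nmr <- c(0.020, 0.025, 0.030, 0.040, 0.050)
  tables <- generate_from_model(true_coef, true_v, rep(0, 5), nmr,
                                cause = "preterm")
  fit <- fit_quadratic(tables, "preterm")
  expect_lt(max(abs(fit$coef - true_coef)), 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("OLS coefficients match brute-force normal equations", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- sample(6:30, 1)
      nmr <- exp(runif(n, log(0.01), log(0.08)))
      q <- matrix(exp(runif(n * 4, -8, -3)), n, 4,
                  dimnames = list(NULL, age_scheme()$labels))
      tables <- lapply(seq_len(n), function(t) {
        quarter_life_table(sprintf("T%02d", t), NA_integer_,
                           cum_q = matrix(sort(q[t, ]), 4, 1,
                                          dimnames = list(age_scheme()$labels,
                                                          "preterm")),
                           nmr = nmr[t], check_envelope = FALSE)
      })
      fit <- fit_quadratic(tables, "preterm")
      z <- log(nmr)
      for (j in 1:4) {
        y <- log(t(sapply(tables, function(tb) tb$cum_q[, "preterm"]))[, j])
        expect_lt(max(abs(fit$coef[j, ] - oracle_ols_quadratic(z, y))), 1e-8)
      }
    })
  }
})

test_that("zero cumulative-probability cells enter the fit through the offset", {
  nmr <- c(0.020, 0.025, 0.030, 0.040)
  tables <- generate_from_model(true_coef, true_v, rep(0, 4), nmr,
                                cause = "sepsis")
  # zero out the youngest age of the first quarter
  tables[[1]]$cum_q[1, "sepsis"] <- 0
  fit <- fit_quadratic(tables, "sepsis", offset = 1e-5)
  z <- log(nmr)
  y <- log(c(1e-5, sapply(tables[-1], function(tb) tb$cum_q[1, "sepsis"])))
  expect_lt(max(abs(fit$coef[1, ] - oracle_ols_quadratic(z, y))), 1e-8)
})

test_that("unidentifiable designs are refused", {
  nmr <- rep(c(0.02, 0.03), each = 2)
  tables <- generate_from_model(true_coef, true_v, rep(0, 4), nmr)
  expect_error(fit_quadratic(tables, "preterm"), "singular design")
  expect_error(fit_quadratic(tables[1:3], "preterm"), "at least 4")
})

test_that("deviation vector estimation matches its construction and oracle", {
  expect_error(estimate_deviation_vector(matrix(0, 6, 4)),
               class = "neonmort_no_deviation_signal")

  # rank-1 residuals factor exactly
  g <- c(0.5, -1.2, 0.3, 0.9, -0.4)
  u <- c(0.2, -0.1, 0.6, 0.5)
  v <- estimate_deviation_vector(outer(g, u))
  expect_lt(max(abs(v - u / u[4])), 1e-10)

  # a deviation profile vanishing at 4 weeks leaves k unidentifiable
  expect_error(estimate_deviation_vector(outer(g, c(1, 1, 1, 0))),
               class = "neonmort_degenerate_deviation")

  withr::with_seed(42, {
    R <- matrix(rnorm(24 * 4), 24, 4)
    v <- estimate_deviation_vector(R)
    vo <- oracle_power_iteration(R)
    vo <- vo / vo[4]
    expect_lt(max(abs(v - vo)), 1e-8)
  })
})

test_that("prediction follows the model equation and ignores v when k = 0", {
  fit <- fit_logquad(synthetic_tables(seed = 2), "asphyxia")
  nmr <- 0.031
  z <- log(nmr)
  manual <- exp(fit$coef[, "a"] + fit$coef[, "b"] * z + fit$coef[, "c"] * z^2)
  p0 <- predict(fit, nmr)
  expect_equal(unname(p0), unname(manual))
  expect_true(all(p0 > 0))

  fit2 <- fit
  fit2$v <- fit$v * 5 + 1
  fit2$v[4] <- 1
  expect_identical(predict(fit2, nmr), p0) # bit-identical: k = 0 never uses v

  expect_error(predict(fit, -0.01), "positive")
  fit3 <- fit
  fit3$v <- NULL
  expect_error(predict(fit3, nmr, k = 0.5), "deviation vector")
})

test_that("k calibration is exact at the last cumulative age", {
  fit <- fit_logquad(synthetic_tables(seed = 5), "preterm")
  nmr <- 0.033

  p0_last <- predict(fit, nmr)[4]
  expect_equal(calibrate_k(fit, nmr, p0_last), 0, tolerance = 1e-12)
  expect_equal(calibrate_k(fit, nmr, 2 * p0_last), log(2), tolerance = 1e-12)
  # a zero observed cause-specific rate calibrates against the offset
  expect_equal(calibrate_k(fit, nmr, 0),
               log(1e-5) - log(unname(p0_last)), tolerance = 1e-12)

  for (cause_nmr in c(0.001, 0.004, 0.02)) {
    for (nmr_t in c(0.02, 0.035, 0.05)) {
      k <- calibrate_k(fit, nmr_t, cause_nmr)
      pred <- predict(fit, nmr_t, k = k)
      expect_lt(abs(pred[4] - cause_nmr) / cause_nmr, 1e-12)
    }
  }
})

test_that("model-generated data with noise recovers b and v", {
  n <- 200
  withr::with_seed(99, {
    nmr <- exp(runif(n, log(0.02), log(0.05)))
    k_t <- rnorm(n, sd = 0.1)
  })
  tables <- generate_from_model(true_coef, true_v, k_t, nmr,
                                noise_sd = 0.01, cause = "preterm", seed = 17)
  fit <- fit_logquad(tables, "preterm")

  z <- log(nmr)
  q <- t(sapply(tables, function(tb) tb$cum_q[, "preterm"]))
  for (j in 1:4) {
    lmfit <- summary(stats::lm(log(q[, j]) ~ z + I(z^2)))
    se_b <- lmfit$coefficients["z", "Std. Error"]
    expect_lt(abs(fit$coef[j, "b"] - true_coef[j, "b"]), 3 * se_b)
  }
  cosine <- sum(fit$v * true_v) / sqrt(sum(fit$v^2) * sum(true_v^2))
  expect_gt(cosine, 0.99)
})

test_that("fits serialize to JSON and back without loss", {
  fit <- fit_logquad(synthetic_tables(seed = 4), "sepsis")
  p <- withr::local_tempfile(fileext = ".json")
  write_logquad_fit(fit, p)
  back <- read_logquad_fit(p)
  expect_identical(back$cause, fit$cause)
  expect_identical(back$quarters, fit$quarters)
  expect_equal(back$coef, fit$coef, tolerance = 1e-15)
  expect_equal(back$v, fit$v, tolerance = 1e-15)
  expect_identical(back$offset, fit$offset)

  p2 <- withr::local_tempfile(fileext = ".json")
  write_logquad_fit(back, p2)
  expect_identical(readLines(p), readLines(p2))
})
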