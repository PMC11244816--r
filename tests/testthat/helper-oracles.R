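# Independent oracles, deliberately sharing no code with the package.

# OLS of y on (1, z, z^2) via explicit normal equations solved by
# hand-rolled Gaussian elimination with partial pivoting.
oracle_ols_quadratic <- function(z, y) {
  X <- cbind(1, z, z^2)
  A <- t(X) %*% X
  b <- t(X) %*% y
  n <- nrow(A)
  M <- cbind(A, b)
  for (col in seq_len(n)) {
    piv <- which.max(abs(M[col:n, col])) + col - 1L
    if (piv != col) M[c(col, piv), ] <- M[c(piv, col), ]
    M[col, ] <- M[col, ] / M[col, col]
    for (row in seq_len(n)[-col]) {
      M[row, ] <- M[row, ] - M[row, col] * M[col, ]
    }
  }
  M[, n + 1L]
}

# Dominant eigenvector of R^T R by plain power iteration.
oracle_power_iteration <- function(R, iters = 500L) {
  A <- t(R) %*% R
  x <- rep(1, ncol(R))
  for (i in seq_len(iters)) {
    x <- A %*% x
    x <- x / sqrt(sum(x^2))
  }
  drop(x)
}

# Naive leave-one-quarter-out cross-validation: plain loops, normal-equation
# OLS, base svd, explicit prediction formulas.
oracle_loqo_cv <- function(tables, causes, offset = 1e-5,
                           rare = c("sepsis", "pneumonia", "congenital")) {
  n <- length(tables)
  ages <- rownames(tables[[1]]$cum_q)
  na <- length(ages)
  bounds <- c(24, 48, 168, 672)
  out <- list()
  abs_acc <- array(0, c(length(causes), na, 3),
                   dimnames = list(causes, ages, c("k0", "best_k", "standard")))
  rel_acc <- array(0, dim(abs_acc), dimnames = dimnames(abs_acc))
  rel_n <- array(0L, dim(abs_acc), dimnames = dimnames(abs_acc))
  for (t in seq_len(n)) {
    train <- tables[-t]
    hold <- tables[[t]]
    z_tr <- log(sapply(train, function(x) x$nmr))
    for (ci in seq_along(causes)) {
      cause <- causes[ci]
      q_tr <- t(sapply(train, function(x) x$cum_q[, cause]))
      q_tr[q_tr == 0] <- offset
      y <- log(q_tr)
      X <- cbind(1, z_tr, z_tr^2)
      coefs <- sapply(seq_len(na), function(j) qr.solve(X, y[, j]))
      resid <- sapply(seq_len(na), function(j) {
        y[, j] - coefs[1, j] - coefs[2, j] * z_tr - coefs[3, j] * z_tr^2
      })
      v <- svd(resid)$v[, 1]
      if (v[na] < 0) v <- -v
      v <- v / v[na]
      z <- log(hold$nmr)
      eta <- coefs[1, ] + coefs[2, ] * z + coefs[3, ] * z^2
      obs <- hold$cum_q[, cause]
      cn <- if (obs[na] == 0) offset else obs[na]
      k <- log(cn) - eta[na]
      preds <- list(k0 = exp(eta), best_k = exp(eta + v * k),
                    standard = obs[na] * (bounds / 672))
      for (mi in 1:3) {
        err <- abs(preds[[mi]] - obs)
        abs_acc[ci, , mi] <- abs_acc[ci, , mi] + err
        pos <- obs > 0
        rel_acc[ci, pos, mi] <- rel_acc[ci, pos, mi] + err[pos] / obs[pos]
        rel_n[ci, pos, mi] <- rel_n[ci, pos, mi] + 1L
      }
    }
  }
  abs_err <- abs_acc / n
  rel_err <- rel_acc / rel_n
  rel_err[causes %in% rare, , ] <- NA_real_
  list(abs_err = abs_err, rel_err = rel_err)
}
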