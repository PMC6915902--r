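# Independent brute-force oracles and small fixture builders.

# OLS via explicit normal equations; independent of stats::lm.
ols_normal_eq <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  b <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- drop(X %*% b)
  n <- length(y); p <- ncol(X)
  res <- y - fitted
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  list(coef = drop(b), fitted = fitted, residuals = res, se = se,
       df = n - p)
}

# two-sided p for H0: beta_j = b0, from the normal-equations fit
ols_p_value <- function(fit, j, b0 = 0) {
  t <- (fit$coef[j] - b0) / fit$se[j]
  unname(2 * pt(-abs(t), df = fit$df))
}

# ridge with unpenalized intercept, via centred normal equations
ridge_normal_eq <- function(X, y, lambda) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  b <- solve(t(Xc) %*% Xc + diag(lambda, ncol(Xc)), t(Xc) %*% (y - ym))
  list(intercept = ym - sum(xm * b), coef = drop(b))
}

random_beta_matrix <- function(n_probes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("cg%07d", seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  beta_matrix(m)
}

write_temp_csv <- function(lines, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}
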