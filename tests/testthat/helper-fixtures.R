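# Shared fixtures and independent oracles for the test suite.

# A minimal scheme with generic tags.
toy_scheme <- function(m = 2L, category = "toy") {
  tag_scheme(sprintf("tag%02d", seq_len(m)), rep(category, m))
}

# A small, well-conditioned feature matrix with a mild group shift.
toy_feature_matrix <- function(n = 30L, m = 2L, shift = 0.01, seed = 99L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(abs(stats::rnorm(n * m, mean = 0.02, sd = 0.005)), n, m)
  x <- x + shift * y
  feature_matrix(x, y)
}

# Independent penalized-likelihood fitter: BFGS on the analytic objective,
# sharing no code with the package's Newton/IRLS routine.
oracle_ridge_fit <- function(x, y, lambda) {
  X <- cbind(1, as.matrix(x))
  pen <- c(0, rep(lambda, ncol(x)))
  negobj <- function(b) {
    eta <- drop(X %*% b)
    -(sum(y * eta - log1p(exp(eta))) - sum(pen * b^2) / 2)
  }
  grad <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    -(drop(crossprod(X, y - p)) - pen * b)
  }
  fit <- stats::optim(numeric(ncol(X)), negobj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  list(intercept = fit$par[1], coefficients = fit$par[-1])
}

# Write a counts TSV from raw pieces (deliberately not via the package
# writer, so reader tests do not depend on it).
write_raw_counts_tsv <- function(path, header, rows) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")),
             path)
}
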