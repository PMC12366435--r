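test_that("the penalized fit matches brute-force maximization", {
  x <- matrix(c(0, 0, 1, 1), 4, 1)
  y <- c(0, 0, 1, 1)
  fit <- fit_logistic(x, y, lambda = 1)
  # brute force: nested grid refinement over (intercept, slope)
  obj <- function(b0, b1) {
    eta <- b0 + b1 * x[, 1]
    sum(y * eta - log1p(exp(eta))) - b1^2 / 2
  }
  lo <- c(-5, -5); hi <- c(5, 5)
  for (round_ in 1:8) {
    g0 <- seq(lo[1], hi[1], length.out = 41)
    g1 <- seq(lo[2], hi[2], length.out = 41)
    vals <- outer(g0, g1, Vectorize(obj))
    best <- arrayInd(which.max(vals), dim(vals))
    step <- c(g0[2] - g0[1], g1[2] - g1[1])
    lo <- c(g0[best[1]], g1[best[2]]) - 2 * step
    hi <- c(g0[best[1]], g1[best[2]]) + 2 * step
  }
  best_pt <- (lo + hi) / 2
  expect_equal(fit$intercept, best_pt[1], tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), best_pt[2], tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("uninformative features leave only the base-rate intercept", {
  x <- matrix(0.5, 6, 1)             # constant feature: no information
  y <- c(1, 0, 0, 1, 0, 1)
  fit <- fit_logistic(x, y, lambda = 0)
  # the optimum is a ridge {b0 + 0.5 b1 = logit(mean y)}; the fitted
  # linear predictor must sit at the base rate for every speaker
  eta <- fit$intercept + 0.5 * unname(fit$coefficients)
  expect_equal(eta, stats::qlogis(mean(y)), tolerance = 1e-6)
  expect_equal(unname(predict(fit, x)$probability),
               rep(mean(y), 6), tolerance = 1e-6)
  # an all-zero feature cannot move from zero
  fit0 <- fit_logistic(matrix(0, 6, 1), y, lambda = 0)
  expect_equal(unname(fit0$coefficients), 0, tolerance = 1e-8)
  expect_equal(fit0$intercept, stats::qlogis(mean(y)), tolerance = 1e-6)
})

test_that("separation at lambda = 0 is flagged with guidance", {
  x <- matrix(c(0, 0, 1, 1), 4, 1)
  y <- c(0, 0, 1, 1)
  expect_warning(fit <- fit_logistic(x, y, lambda = 0, maxit = 30),
                 "lambda > 0")
  expect_false(fit$converged)
})

test_that("a near-square fit stays finite and converges", {
  sc <- default_tag_scheme()
  fm <- normalize_features(generate_corpus(synthetic_config(sc, seed = 8L)))
  fit <- fit_logistic(fm, lambda = 1)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
  expect_length(fit$coefficients, 135L)
  expect_lt(fit$grad_norm, 1e-8)
})

test_that("the optimizer's objective is monotone non-decreasing", {
  for (seed in 1:5) {
    fm <- toy_feature_matrix(n = 40, m = 5, seed = seed)
    fit <- fit_logistic(fm, lambda = 0.5)
    expect_true(all(diff(fit$objective_trace) >= -1e-9))
  }
})

test_that("stronger penalties shrink the coefficient norm", {
  fm <- toy_feature_matrix(n = 60, m = 4, shift = 0.02)
  norms <- vapply(c(0.01, 0.1, 1, 10),
                  function(l) sqrt(sum(fit_logistic(fm, lambda = l)$coefficients^2)),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("label swap negates the unpenalized solution", {
  fm <- toy_feature_matrix(n = 50, m = 2, shift = 0.004)
  f1 <- fit_logistic(fm$x, fm$y, lambda = 0)
  f2 <- fit_logistic(fm$x, 1L - fm$y, lambda = 0)
  expect_equal(f2$intercept, -f1$intercept, tolerance = 1e-6)
  expect_equal(f2$coefficients, -f1$coefficients, tolerance = 1e-6)
})

test_that("the fit agrees with independent optimizers", {
  fm <- toy_feature_matrix(n = 80, m = 3, shift = 0.004)
  fit <- fit_logistic(fm, lambda = 2)
  oracle <- oracle_ridge_fit(fm$x, fm$y, lambda = 2)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-5)
  expect_equal(unname(fit$coefficients), oracle$coefficients,
               tolerance = 1e-4)
  # unpenalized fit against glm()
  f0 <- fit_logistic(fm$x, fm$y, lambda = 0)
  g <- stats::glm(fm$y ~ fm$x, family = stats::binomial())
  expect_equal(f0$intercept, unname(stats::coef(g)[1]), tolerance = 1e-6)
  expect_equal(unname(f0$coefficients), unname(stats::coef(g)[-1]),
               tolerance = 1e-6)
})

test_that("predictions follow the logistic formula", {
  fm <- toy_feature_matrix(n = 10, m = 3)
  fit <- list(intercept = 0,
              coefficients = stats::setNames(rep(0, 3), fm$tag_names),
              lambda = 1)
  class(fit) <- "tag_logistic"
  pr <- predict(fit, fm)
  expect_equal(unname(pr$probability), rep(0.5, 10))
  expect_identical(pr$label, rep(1L, 10))   # ties go to the positive class

  fit$intercept <- -50
  expect_true(all(predict(fit, fm)$probability < 1e-20))

  set.seed(31)
  fit$intercept <- 0.3
  fit$coefficients[] <- stats::rnorm(3)
  pr <- predict(fit, fm)
  manual <- 1 / (1 + exp(-(0.3 + fm$x %*% fit$coefficients)))
  expect_equal(pr$probability, drop(manual), tolerance = 1e-12)

  expect_error(predict(fit, fm$x[, 1:2]), "expects")
})

test_that("confusion-matrix metrics follow their identities", {
  m <- evaluate_classifier(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(m[c("accuracy", "precision", "sensitivity",
                          "specificity")]),
               c(accuracy = 1, precision = 1, sensitivity = 1,
                 specificity = 1))
  m <- evaluate_classifier(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 1)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1)
  expect_identical(c(m$tp, m$fp, m$tn, m$fn), c(1L, 0L, 2L, 1L))

  expect_warning(m <- evaluate_classifier(c(1, 0, 1), c(0, 0, 0)),
                 "precision undefined")
  expect_true(is.nan(m$precision))
  expect_error(evaluate_classifier(c(1, 0), c(1, 0, 0)), "equal length")
  expect_error(evaluate_classifier(c(1, 2), c(1, 0)), "binary")
})

test_that("cross-validation is stratified, seeded and guarded", {
  fm <- toy_feature_matrix(n = 40, m = 3, shift = 0.02)
  m1 <- cross_validate(fm, k = 5, seed = 42)
  m2 <- cross_validate(fm, k = 5, seed = 42)
  expect_identical(attr(m1, "folds"), attr(m2, "folds"))
  expect_identical(unclass(m1), unclass(m2))
  # every fold contains both classes
  folds <- attr(m1, "folds")
  for (f in 1:5)
    expect_identical(sort(unique(fm$y[folds == f])), c(0L, 1L))
  small <- feature_matrix(matrix(runif(12), 6, 2),
                          c(1, 1, 1, 1, 0, 0))
  expect_error(cross_validate(small, k = 5), "at least k")
})
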