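test_that("pvalue_from_moments implements the two-sided normal tail", {
  expect_equal(pvalue_from_moments(0, 1), 1)
  expect_equal(pvalue_from_moments(0, 1e-9), 1)
  # published rows that reproduce at printed precision
  expect_equal(round(pvalue_from_moments(-0.0741, 0.0214), 4), 0.0005)
  expect_equal(round(pvalue_from_moments(-0.0512, 0.0177), 4), 0.0038)
  expect_error(pvalue_from_moments(1, 0), "strictly positive")
  expect_error(pvalue_from_moments(1, -2), "strictly positive")
  expect_error(pvalue_from_moments(NA, 1), "finite")
})

test_that("the p-value is scale-invariant and monotone in |z|", {
  set.seed(5)
  means <- stats::rnorm(50)
  sds <- stats::rexp(50) + 0.1
  p <- pvalue_from_moments(means, sds)
  expect_true(all(p >= 0 & p <= 1))
  for (c_ in c(0.001, 3, 1e6))
    expect_equal(pvalue_from_moments(c_ * means, c_ * sds), p)
  z <- sort(abs(means) / sds)
  expect_true(all(diff(pvalue_from_moments(z, 1)) < 0))
})

test_that("the normal tail matches quadrature of the normal density", {
  for (z in c(0.5, 1.3, 2.7, 3.46)) {
    tail_quad <- stats::integrate(stats::dnorm, z, Inf,
                                  rel.tol = 1e-13)$value
    expect_equal(pvalue_from_moments(z, 1), 2 * tail_quad,
                 tolerance = 1e-10)
  }
})

test_that("a single-iteration bootstrap is degenerate but reported", {
  fm <- toy_feature_matrix(n = 12, m = 2)
  res <- bootstrap_coefficients(fm, B = 1, seed = 4)
  expect_identical(attr(res, "B"), 1L)
  expect_true(all(res$sd == 0))
  expect_true(all(is.na(res$p_value)))
  expect_false(any(res$significant))
  # the recorded mean is the single refit on the same seeded resample
  set.seed(4L)
  n <- 12L
  repeat {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(fm$y[idx])) == 2L) break
  }
  refit <- fit_logistic(fm$x[idx, ], fm$y[idx], lambda = 1)
  expect_equal(res$mean, unname(refit$coefficients))
  expect_error(select_discriminators(res), "B = 1")
})

test_that("bootstrap moments match an independent re-enumeration", {
  fm <- toy_feature_matrix(n = 12, m = 2, shift = 0.015, seed = 13)
  B <- 200L
  res <- bootstrap_coefficients(fm, B = B, lambda = 1, seed = 31)

  # independent implementation: same documented RNG protocol, fits by BFGS
  set.seed(31L)
  n <- nrow(fm$x)
  coefs <- matrix(NA_real_, B, 2)
  n_failed <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(fm$y[idx])) == 2L) break
      n_failed <- n_failed + 1L
    }
    coefs[b, ] <- oracle_ridge_fit(fm$x[idx, , drop = FALSE], fm$y[idx],
                                   lambda = 1)$coefficients
  }
  expect_identical(attr(res, "n_failed"), n_failed)
  expect_equal(res$mean, colMeans(coefs), tolerance = 1e-5)
  expect_equal(res$sd, apply(coefs, 2, stats::sd), tolerance = 1e-4)
})

test_that("the bootstrap is bit-identical across runs at a fixed seed", {
  fm <- toy_feature_matrix(n = 20, m = 3)
  a <- bootstrap_coefficients(fm, B = 50, seed = 9)
  b <- bootstrap_coefficients(fm, B = 50, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- bootstrap_coefficients(fm, B = 50, seed = 10)
  expect_false(identical(a$mean, c_$mean))
})

test_that("reported p-values are consistent with reported moments", {
  fm <- toy_feature_matrix(n = 30, m = 4, shift = 0.01)
  res <- bootstrap_coefficients(fm, B = 80, seed = 2)
  expect_identical(res$p_value, pvalue_from_moments(res$mean, res$sd))
  expect_identical(res$significant, res$p_value < attr(res, "alpha"))
  expect_equal(res$z, res$mean / res$sd)
})

test_that("stratified resampling never degenerates", {
  fm <- toy_feature_matrix(n = 14, m = 2)
  res <- bootstrap_coefficients(fm, B = 100, seed = 6, stratified = TRUE)
  expect_identical(attr(res, "n_failed"), 0L)
})

test_that("single-class resamples are redrawn and counted", {
  set.seed(1)
  x <- matrix(stats::runif(40), 20, 2)
  y <- c(1L, rep(0L, 19))            # P(resample misses the positive) ~ 1/e
  fm <- feature_matrix(x, y)
  res <- bootstrap_coefficients(fm, B = 60, seed = 1)
  expect_gt(attr(res, "n_failed"), 0L)
  expect_true(all(is.finite(res$mean)))
  expect_error(bootstrap_coefficients(fm, B = 0), ">= 1")
})

test_that("discriminator selection is strict, ordered and guarded", {
  res <- data.frame(tag = c("a", "b", "c"),
                    mean = c(-0.1, 0.05, 0.01),
                    sd = c(0.02, 0.03, 0.05),
                    p_value = c(0.0005, 0.05, 0.9))
  sel <- select_discriminators(res, alpha = 0.05)
  expect_identical(sel$tag, "a")           # 0.05 is not < 0.05
  sel_all <- select_discriminators(res, alpha = 1 - 1e-12)
  expect_identical(sel_all$tag, c("a", "b", "c"))
  expect_error(select_discriminators(res, alpha = 0), "0, 1")
  expect_error(select_discriminators(res, alpha = 1), "0, 1")
  # ordering: ascending p, ties by input order
  res2 <- data.frame(tag = c("t1", "t2", "t3", "t4"),
                     mean = 1, sd = 1,
                     p_value = c(0.02, 0.01, 0.02, 0.001))
  expect_identical(select_discriminators(res2)$tag,
                   c("t4", "t2", "t1", "t3"))
  # Benjamini-Hochberg extension tightens the selection
  res3 <- data.frame(tag = letters[1:4], mean = 1, sd = 1,
                     p_value = c(0.001, 0.04, 0.045, 0.9))
  expect_lte(nrow(select_discriminators(res3, adjust = "BH")),
             nrow(select_discriminators(res3)))
})

test_that("the structural-level filter subsets without silent drops", {
  sc <- default_tag_scheme()
  t1 <- table1_discriminators()
  filtered <- filter_structural_level(t1$tag, sc, level = "clause_phrase")
  expect_length(filtered, 20L)
  expect_identical(attr(filtered, "unclassified"), character(0))

  # level = "all" is the identity
  same <- filter_structural_level(t1$tag, sc, level = "all")
  expect_identical(as.character(same), t1$tag)

  expect_length(filter_structural_level(character(0), sc,
                                        level = "clause_phrase"), 0L)

  # unannotated tags are listed, not dropped silently
  mixed <- c(t1$tag[4], sc$tags[135])    # placeholder has no level
  expect_message(
    out <- filter_structural_level(mixed, sc, level = "clause_phrase"),
    "unclassified")
  expect_identical(as.character(out), t1$tag[4])
  expect_identical(attr(out, "unclassified"), sc$tags[135])

  # data-frame selections keep their columns
  sel <- data.frame(tag = t1$tag, mean = t1$mean, sd = t1$sd,
                    p_value = t1$p_value)
  out_df <- filter_structural_level(sel, sc, level = "clause_phrase")
  expect_identical(nrow(out_df), 20L)
  expect_named(out_df, c("tag", "mean", "sd", "p_value"))

  expect_error(filter_structural_level("nope", sc), "not in scheme")
})
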