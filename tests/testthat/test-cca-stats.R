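# the published worked example: canonical correlations printed for the
# n = 131, p = 63, q = 5 full-sample model
ref <- reference_cohort_values()

test_that("Wilks' lambda reproduces the published value and trivial cases", {
  expect_equal(wilks_lambda(ref$canonical_correlations), 0.015,
               tolerance = 0.001 / 0.015)
  expect_equal(wilks_lambda(rep(0, 5)), 1)
  expect_equal(wilks_lambda(0.5), 0.75)
  expect_error(wilks_lambda(c(0.5, 1.2)), "outside")
})

test_that("Rao's F matches the published statistic and the q = 1 regression F", {
  lam <- wilks_lambda(ref$canonical_correlations)
  rao <- rao_f(lam, ref$n, ref$p, ref$q)
  expect_equal(rao$df1, 315)
  expect_equal(rao$df2, 319)
  expect_equal(rao$f, 1.35, tolerance = 0.02 / 1.35)
  expect_equal(rao_f(1, 50, 4, 3)$f, 0)
  # q = 1: Rao's F is the overall regression F
  set.seed(4)
  x <- matrix(rnorm(60 * 4), 60)
  y <- x %*% rnorm(4) + rnorm(60)
  r2 <- summary(lm(y ~ x))$r.squared
  fstat <- summary(lm(y ~ x))$fstatistic
  rao1 <- rao_f(1 - r2, 60, 4, 1)
  expect_equal(rao1$f, unname(fstat[1]), tolerance = 1e-8)
  expect_equal(rao1$df1, unname(fstat[2]))
  expect_equal(rao1$df2, unname(fstat[3]))
})

test_that("Pillai's trace matches the published statistic and trivial cases", {
  pil <- pillai_trace(ref$canonical_correlations, ref$n, ref$p, ref$q)
  expect_equal(pil$v, 2.81, tolerance = 0.01 / 2.81)
  expect_equal(pil$f, 1.36, tolerance = 0.02 / 1.36)
  expect_equal(pil$df1, 315)
  expect_equal(pil$df2, 335)
  expect_equal(pillai_trace(rep(0, 3), 50, 6, 3)$v, 0)
  expect_equal(pillai_trace(rep(0, 3), 50, 6, 3)$f, 0)
  expect_equal(pillai_trace(c(0.999999, 0, 0), 50, 6, 3)$v, 1,
               tolerance = 1e-4)
})

test_that("Bartlett's sequential chi-squared matches the published values", {
  b1 <- bartlett_chi2(ref$canonical_correlations, 1, ref$n, ref$p, ref$q)
  expect_equal(b1$chi2, 402.24, tolerance = 0.01)
  expect_equal(b1$df, 315)
  b2 <- bartlett_chi2(ref$canonical_correlations, 2, ref$n, ref$p, ref$q)
  expect_equal(b2$chi2, 294.58, tolerance = 0.01)
  expect_equal(b2$df, 248)
  expect_equal(bartlett_chi2(rep(0, 4), 1, 100, 8, 4)$chi2, 0)
})

test_that("rho^2 equals 1 - lambda and the report is internally consistent", {
  set.seed(6)
  x <- matrix(rnorm(80 * 6), 80)
  y <- matrix(rnorm(80 * 4), 80) + 0.4 * x[, 1:4]
  fit <- fit_cca(x, y)
  report <- cca_significance(fit)
  expect_identical(report$wilks$rho_sq, 1 - report$wilks$lambda)
  # clinical adequacies over all s = q variates partition the variance
  expect_equal(sum(report$adequacy$adequacy_y), 100, tolerance = 0.1)
  expect_equal(report$adequacy$redundancy,
               report$adequacy$adequacy_y * fit$cor^2, tolerance = 1e-10)
})

test_that("redundancy matches a per-variable regression oracle", {
  set.seed(8)
  x <- matrix(rnorm(70 * 5), 70)
  y <- matrix(rnorm(70 * 3), 70) + 0.5 * x[, 1:3]
  fit <- fit_cca(x, y)
  adq <- adequacy_redundancy(fit)
  ys <- scale(y)
  for (i in seq_along(fit$cor)) {
    # variance of each standardized y explained by brain variate i
    r2 <- vapply(seq_len(ncol(y)), function(j) {
      summary(lm(ys[, j] ~ fit$scores_x[, i]))$r.squared
    }, numeric(1))
    expect_equal(unname(adq$redundancy[i]), 100 * mean(r2),
                 tolerance = 1e-6)
  }
  # q = 1: single variate is fully adequate
  fit1 <- fit_cca(x, cbind(rnorm(70)))
  expect_equal(unname(adequacy_redundancy(fit1)$adequacy_y), 100,
               tolerance = 1e-10)
})

test_that("variate sorting orders by Bartlett significance consistently", {
  set.seed(10)
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rnorm(60 * 5), 60)
    y <- matrix(rnorm(60 * 3), 60) + 0.3 * x[, 1:3]
    fit <- fit_cca(x, y)
    report <- cca_significance(fit)
    sorted <- sort_variates(fit, report)
    expect_true(all(diff(sorted$report$bartlett$p_value) >= 0))
    # scores still match weights after permutation
    expect_equal(sorted$fit$scores_x, scale(x) %*% sorted$fit$wx,
                 tolerance = 1e-10, ignore_attr = TRUE)
    # canonical correlations travel with their variates
    expect_equal(sorted$fit$cor, fit$cor[sorted$fit$order])
  }
  # an already-sorted model keeps the identity permutation
  set.seed(2)
  x <- matrix(rnorm(100 * 4), 100)
  y <- matrix(rnorm(100 * 3), 100) + x[, 1:3] %*% diag(c(1, 0.5, 0.2))
  fit <- fit_cca(x, y)
  sorted <- sort_variates(fit, cca_significance(fit))
  expect_equal(sorted$fit$order, 1:3)
})

test_that("Bartlett test is calibrated under independence", {
  rej <- vapply(1:500, function(s) {
    set.seed(s)
    x <- matrix(rnorm(200 * 6), 200)
    y <- matrix(rnorm(200 * 3), 200)
    rho <- cancor(x, y)$cor
    bartlett_chi2(rho, 1, 200, 6, 3)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})
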