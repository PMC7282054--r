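test_that("tucker congruence formula and bands", {
  expect_equal(tucker_congruence(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(tucker_congruence(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(tucker_congruence(c(1, 2, 3), c(3, 2, 1)), 10 / 14,
               tolerance = 1e-12)
  # invariant to common positive scaling
  expect_equal(tucker_congruence(c(0.2, -0.4, 0.1), 7 * c(0.5, 0.1, -0.3)),
               tucker_congruence(c(0.2, -0.4, 0.1), c(0.5, 0.1, -0.3)),
               tolerance = 1e-12)
  expect_error(tucker_congruence(c(0, 0), c(1, 1)), "zero")
})

test_that("fisher z comparison matches the closed form and degenerate case", {
  res <- fisher_z_compare(0.5, 53, 0.0, 53)
  expect_equal(res$z, atanh(0.5) / sqrt(2 / 50), tolerance = 1e-12)
  expect_equal(res$z, 2.747, tolerance = 1e-3)
  same <- fisher_z_compare(0.3, 40, 0.3, 60)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 0.5)
  expect_equal(fisher_z_compare(0.4, 30, 0.1, 30, tail = "two")$p_value,
               2 * fisher_z_compare(0.4, 30, 0.1, 30)$p_value)
  expect_error(fisher_z_compare(1, 30, 0.5, 30), "below 1")
})

test_that("fisher z type-I error is calibrated under a common correlation", {
  set.seed(77)
  rej <- vapply(1:2000, function(i) {
    z <- rnorm(65); w <- rnorm(65)
    x1 <- 0.3 * z + sqrt(1 - 0.09) * rnorm(65)
    x2 <- 0.3 * w + sqrt(1 - 0.09) * rnorm(65)
    fisher_z_compare(cor(z, x1), 65, cor(w, x2), 65,
                     alternative = "greater")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("full-sample mask reproduces the model loadings exactly", {
  set.seed(12)
  x <- matrix(rnorm(60 * 5), 60)
  colnames(x) <- paste0("f", 1:5)
  y <- matrix(rnorm(60 * 3), 60) + 0.4 * x[, 1:3]
  fit <- fit_cca(x, y)
  gl <- forward_loadings(x, y, fit, rep(TRUE, 60), "all")
  expect_equal(unname(gl$loadings_x), unname(fit$loadings_x),
               tolerance = 1e-10)
  expect_equal(unname(gl$loadings_y), unname(fit$loadings_y),
               tolerance = 1e-10)
  # brute-force per-entry correlation oracle on a subgroup
  mask <- rep(c(TRUE, FALSE), 30)
  gl2 <- forward_loadings(x, y, fit, mask)
  for (j in 1:5) {
    for (i in 1:3) {
      expect_equal(gl2$loadings_x[j, i],
                   cor(x[mask, j], fit$scores_x[mask, i]),
                   tolerance = 1e-10)
    }
  }
})

test_that("identical duplicated groups give phi = 1, z = 0, class equal", {
  set.seed(13)
  x0 <- matrix(rnorm(40 * 5), 40)
  colnames(x0) <- paste0("f", 1:5)
  y0 <- matrix(rnorm(40 * 3), 40) + 0.5 * x0[, 1:3]
  x <- rbind(x0, x0); y <- rbind(y0, y0)
  fit <- fit_cca(x, y)
  cmp <- compare_groups(x, y, fit, rep(c(TRUE, FALSE), each = 40))
  expect_equal(cmp$congruence$phi_x, rep(1, 3), tolerance = 1e-10)
  expect_equal(cmp$congruence$phi_y, rep(1, 3), tolerance = 1e-10)
  expect_true(all(cmp$congruence$class_x == "equal"))
  expect_true(all(abs(cmp$tests$z) < 1e-10))
  expect_false(any(cmp$tests$significant))
})

test_that("group loadings track full-sample loadings for exchangeable data", {
  set.seed(14)
  x <- matrix(rnorm(1000 * 8), 1000)
  colnames(x) <- paste0("f", 1:8)
  y <- matrix(rnorm(1000 * 4), 1000) + 0.4 * x[, 1:4]
  fit <- fit_cca(x, y)
  mask <- sample(rep(c(TRUE, FALSE), 500))
  gl <- forward_loadings(x, y, fit, mask)
  close <- abs(gl$loadings_x - fit$loadings_x) <= 0.1
  expect_gte(mean(close), 0.95)
})

test_that("null splits give calibrated loading-difference tests", {
  set.seed(15)
  x <- matrix(rnorm(400 * 6), 400)
  colnames(x) <- paste0("f", 1:6)
  y <- matrix(rnorm(400 * 3), 400) + 0.4 * x[, 1:3]
  fit <- fit_cca(x, y)
  rates <- vapply(1:200, function(i) {
    mask <- sample(rep(c(TRUE, FALSE), 200))
    cmp <- compare_groups(x, y, fit, mask)
    # directional rejection rate (carrier > non-carrier) is calibrated;
    # the observed-direction convention used for reporting doubles it
    mean(cmp$tests$z > qnorm(0.95))
  }, numeric(1))
  expect_gte(mean(rates), 0.03)
  expect_lte(mean(rates), 0.08)
})

test_that("planted group-divergent structure dissociates brain and clinical congruence", {
  d <- simulate_group_divergent_data(n_per_group = 200, seed = 5)
  fit <- fit_cca(d$x, d$y)
  sorted <- sort_variates(fit, cca_significance(fit))
  cmp <- compare_groups(d$x, d$y, sorted$fit, d$carrier_mask,
                        variates = 1:2)
  expect_lt(mean(cmp$congruence$phi_x[1:2]), 0.5)
  expect_gt(mean(cmp$congruence$phi_y[1:2]), 0.9)
})

test_that("masks and group sizes are validated", {
  set.seed(16)
  x <- matrix(rnorm(30 * 4), 30)
  y <- matrix(rnorm(30 * 2), 30)
  fit <- fit_cca(x, y)
  expect_error(compare_groups(x, y, fit, rep(TRUE, 30)), "both groups")
  expect_error(forward_loadings(x, y, fit, c(rep(TRUE, 3), rep(FALSE, 27))),
               "fewer than 5")
})
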