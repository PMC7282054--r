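test_that("factor coding of the 2x2 design is sum-to-zero with product interaction", {
  design <- build_design(toy_cell_cohort(),
                         design_spec(covariates = character(0)))
  x <- design$X
  expect_equal(sort(unique(x[, "del22q11"])), c(-0.5, 0.5))
  expect_equal(x[, "interaction"], x[, "del22q11"] * x[, "asd"])
  expect_equal(colnames(x), c("intercept", "del22q11", "asd", "interaction"))
})

test_that("continuous covariates are mean-centred and rank is 11", {
  cohort <- simulate_cohort(seed = 5)
  design <- build_design(cohort, design_spec(metric = "CT"))
  x <- design$X
  for (cv in c("fsiq", "age", "age2", "total_brain")) {
    expect_lt(abs(sum(x[, cv])), 1e-8)
  }
  # intercept + del + asd + interaction + gender + 2 site dummies + 4 covs
  expect_equal(design$rank, 11)
  expect_equal(design$rank, qr(x)$rank)
})

test_that("rank-deficient designs report the offending columns", {
  cohort <- simulate_cohort(seed = 5)
  cohort$age2 <- 2 * cohort$age  # perfectly collinear after centering
  expect_error(build_design(cohort, design_spec(metric = "CT")),
               "rank deficient")
})

test_that("noiseless linear responses are recovered exactly", {
  cohort <- simulate_cohort(seed = 2)
  design <- build_design(cohort, design_spec(metric = "CT"))
  age_c <- design$X[, "age"]
  y <- matrix(2 + 3 * age_c, nrow(cohort), 5)
  fit <- fit_vertex_glm(design, y)
  expect_equal(unname(fit$coefficients["age", ]), rep(3, 5),
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["intercept", ]), rep(2, 5),
               tolerance = 1e-10)
  # residual variance is (numerically) nil: t is non-finite or extreme,
  # never a plausible fabricated statistic
  tv <- contrast_tmap(fit, "age")$values
  expect_true(all(!is.finite(tv) | abs(tv) > 1e5))
})

test_that("per-vertex OLS matches the normal-equations oracle", {
  set.seed(42)
  for (rep in 1:3) {
    x <- cbind(intercept = 1, matrix(rnorm(20 * 3), 20,
                                     dimnames = list(NULL, c("a", "b", "c"))))
    design <- structure(list(X = x, rank = 4L,
                             term_map = as.list(seq_len(4))),
                        class = "design_matrix")
    y <- matrix(rnorm(20 * 5), 20)
    fit <- fit_vertex_glm(design, y)
    beta_oracle <- solve(crossprod(x)) %*% crossprod(x, y)
    expect_equal(unname(fit$coefficients), unname(beta_oracle),
                 tolerance = 1e-8)
    # SE oracle from lm
    sfit <- summary(lm(y[, 1] ~ x - 1))
    expect_equal(unname(fit$standard_errors[, 1]),
                 unname(sfit$coefficients[, 2]), tolerance = 1e-8)
  }
})

test_that("consistent row permutation leaves t maps unchanged", {
  cohort <- simulate_cohort(seed = 9)
  mesh <- fixture_mesh(2)
  m <- simulate_vertex_metrics(cohort, mesh, noise_sd = c(CV = 20, SA = 5,
                                                          CT = 0.2), seed = 4)
  design <- build_design(cohort, design_spec(metric = "CT"))
  fit1 <- fit_vertex_glm(design, m$CT)
  perm <- sample(nrow(cohort))
  design2 <- build_design(cohort[perm, ], design_spec(metric = "CT"))
  fit2 <- fit_vertex_glm(design2, m$CT[perm, ])
  expect_equal(contrast_tmap(fit1, "asd")$values,
               contrast_tmap(fit2, "asd")$values, tolerance = 1e-9)
})

test_that("OLS residuals are orthogonal to the design", {
  cohort <- simulate_cohort(seed = 9)
  design <- build_design(cohort, design_spec(metric = "CV"))
  set.seed(1)
  y <- matrix(rnorm(nrow(cohort) * 10), nrow(cohort))
  fit <- fit_vertex_glm(design, y)
  xs <- scale(design$X[, -1])
  expect_lt(max(abs(crossprod(cbind(1, xs), fit$residuals))), 1e-8)
})

test_that("t maps are invariant to response scaling and covariate rescaling", {
  cohort <- simulate_cohort(seed = 13)
  design <- build_design(cohort, design_spec(metric = "CT"))
  set.seed(2)
  y <- matrix(rnorm(nrow(cohort) * 8), nrow(cohort)) + 2
  t1 <- contrast_tmap(fit_vertex_glm(design, y), "del22q11")$values
  t2 <- contrast_tmap(fit_vertex_glm(design, 10 * y), "del22q11")$values
  expect_equal(t1, t2, tolerance = 1e-10)
  cohort2 <- dplyr::mutate(cohort, fsiq = (fsiq - 100) / 15,
                           age = age * 12, age2 = age2 * 144)
  design2 <- build_design(cohort2, design_spec(metric = "CT"))
  t3 <- contrast_tmap(fit_vertex_glm(design2, y), "del22q11")$values
  expect_equal(t1, t3, tolerance = 1e-8)
})

test_that("with balanced cells the del22q11 coefficient is the marginal mean difference", {
  cohort <- simulate_cohort(cohort_config(c(10L, 10L, 10L, 10L)), seed = 3)
  mu <- c(`00` = 1, `01` = 2, `10` = 4, `11` = 7)
  y <- matrix(mu[paste0(cohort$del22q11, cohort$asd)], ncol = 1)
  design <- build_design(
    dplyr::select(cohort, subject_id, group, del22q11, asd),
    design_spec(covariates = character(0)))
  fit <- fit_vertex_glm(design, y)
  carrier_mean <- mean(y[cohort$del22q11 == 1, ])
  noncarrier_mean <- mean(y[cohort$del22q11 == 0, ])
  expect_equal(unname(fit$coefficients["del22q11", 1]),
               carrier_mean - noncarrier_mean, tolerance = 1e-10)
})

test_that("type-I error of the term t test is calibrated", {
  # 500 null refits at a single vertex
  cohort <- simulate_cohort(seed = 17)
  design <- build_design(cohort, design_spec(metric = "CT"))
  set.seed(31)
  rej <- vapply(1:500, function(i) {
    y <- matrix(rnorm(nrow(cohort)), ncol = 1)
    fit <- fit_vertex_glm(design, y)
    abs(contrast_tmap(fit, "asd")$values) > qt(0.975, fit$dof)
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("effect size maps follow d = t * sqrt(1/n_a + 1/n_b)", {
  cohort <- simulate_cohort(cohort_config(c(25L, 25L, 25L, 25L)), seed = 19)
  design <- build_design(cohort, design_spec(metric = "CT"))
  set.seed(5)
  y <- matrix(rnorm(100 * 4), 100)
  fit <- fit_vertex_glm(design, y)
  tmap <- contrast_tmap(fit, "del22q11")
  dmap <- effect_size_map(fit, "del22q11")
  expect_equal(dmap$values, tmap$values * sqrt(1 / 50 + 1 / 50),
               tolerance = 1e-12)
  expect_equal(dmap$kind, "cohen_d")
  # t = 2 with equal 50/50 groups gives d = 0.4
  expect_equal(2 * sqrt(2 / 50), 0.4, tolerance = 1e-12)
  expect_error(effect_size_map(fit, "interaction"), "two-level factor")
})

test_that("planted main effect reproduces the two-sample d oracle", {
  cohort <- simulate_cohort(cohort_config(c(10L, 10L, 10L, 10L)), seed = 23)
  mesh <- fixture_mesh(2)
  eff <- planted_effect("del22q11", 30, 30, 0.5, "CT")
  m <- simulate_vertex_metrics(
    cohort, mesh, effects = list(eff),
    noise_sd = c(CV = 0, SA = 0, CT = 0.2), seed = 6)
  # remove the baseline differences so the only signal is the planted term
  ct <- m$CT - matrix(cohort$mean_ct, nrow(cohort), nrow(mesh$vertices))
  # two-group model only: its residual SD is exactly the pooled SD
  design <- build_design(
    dplyr::select(cohort, subject_id, group, del22q11, asd),
    design_spec(interaction = FALSE, covariates = character(0),
                factors = "del22q11", nuisance_factors = FALSE))
  fit <- fit_vertex_glm(design, ct)
  dmap <- effect_size_map(fit, "del22q11")
  a <- ct[cohort$del22q11 == 1, 30]
  b <- ct[cohort$del22q11 == 0, 30]
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  d_oracle <- (mean(a) - mean(b)) / sp
  expect_equal(dmap$values[30], d_oracle, tolerance = 1e-6)
})
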