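test_that("resel estimation recovers the smoothness of simulated fields", {
  mesh <- fixture_mesh(3)
  # white noise: local FWHM of the order of the edge length
  set.seed(21)
  res_white <- estimate_resels(mesh, matrix(rnorm(40 * nrow(mesh$vertices)),
                                            40), dof = 39)
  med_fwhm <- median(res_white$per_triangle$local_fwhm)
  expect_gt(med_fwhm, 0.5 * mesh$mean_edge_length)
  expect_lt(med_fwhm, 2 * mesh$mean_edge_length)
  # smoothed noise: total resels close to area / fwhm^2
  fwhm <- 36
  sm <- fixture_smoother(3, fwhm)
  reps <- vapply(1:10, function(i) {
    set.seed(i)
    y <- smooth_null_maps(40, mesh, sm)
    attr(estimate_resels(mesh, y, 39), "total_resels")
  }, numeric(1))
  theory <- sum(mesh$triangle_areas) / fwhm^2
  expect_lt(abs(mean(reps) - theory) / theory, 0.3)
})

test_that("doubling the smoothing kernel divides resels by about four", {
  mesh <- fixture_mesh(3)
  sm1 <- fixture_smoother(3, 24)
  sm2 <- fixture_smoother(3, 48)
  r <- vapply(1:8, function(i) {
    set.seed(100 + i)
    y1 <- smooth_null_maps(40, mesh, sm1)
    y2 <- smooth_null_maps(40, mesh, sm2)
    attr(estimate_resels(mesh, y1, 39), "total_resels") /
      attr(estimate_resels(mesh, y2, 39), "total_resels")
  }, numeric(1))
  expect_gt(mean(r), 3)
  expect_lt(mean(r), 5)
})

test_that("degenerate residuals are rejected", {
  mesh <- fixture_mesh(2)
  one <- rnorm(nrow(mesh$vertices))
  res <- matrix(one, 10, nrow(mesh$vertices), byrow = TRUE)
  expect_error(estimate_resels(mesh, res, 9), "rank")
})

test_that("doubling mesh resolution leaves total resels stable", {
  fwhm <- 30
  totals <- vapply(c(3, 4), function(sub) {
    mesh <- fixture_mesh(sub)
    sm <- fixture_smoother(sub, fwhm)
    set.seed(5)
    y <- smooth_null_maps(60, mesh, sm)
    attr(estimate_resels(mesh, y, 59), "total_resels")
  }, numeric(1))
  expect_lt(abs(totals[1] - totals[2]) / totals[2], 0.15)
})

test_that("sub-threshold maps give an empty cluster table", {
  mesh <- fixture_mesh(2)
  sm <- structure(list(values = rep(0.5, nrow(mesh$vertices)), kind = "t",
                       term = "asd", dof = 30), class = "statmap")
  tab <- find_clusters(sm, mesh, primary_p = 0.001)
  expect_equal(nrow(tab), 0)
})

test_that("planted disjoint blobs are recovered as separate signed clusters", {
  mesh <- fixture_mesh(3)
  nv <- nrow(mesh$vertices)
  d1 <- mesh_geodesic(mesh, 10)
  # antipodal seed: the farthest vertex from seed 1
  far <- which.max(d1)
  d2 <- mesh_geodesic(mesh, far)
  vals <- rep(0, nv)
  vals[d1 < 20] <- 6
  vals[d2 < 20] <- -6
  sm <- structure(list(values = vals, kind = "t", term = "interaction",
                       dof = 40), class = "statmap")
  tab <- find_clusters(sm, mesh, primary_p = 0.001, sign = "both")
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$sign, c("positive", "negative"))
  pos <- tab$vertices[[which(tab$sign == "positive")]]
  expect_setequal(pos, which(d1 < 20))
  neg <- tab$vertices[[which(tab$sign == "negative")]]
  expect_setequal(neg, which(d2 < 20))
  # two positive blobs stay distinct
  vals2 <- rep(0, nv)
  vals2[d1 < 20] <- 6
  vals2[d2 < 20] <- 6
  sm2 <- structure(list(values = vals2, kind = "t", term = "interaction",
                        dof = 40), class = "statmap")
  tab2 <- find_clusters(sm2, mesh, primary_p = 0.001, sign = "positive")
  expect_equal(nrow(tab2), 2)
})

test_that("zero-extent clusters get corrected p of 1 and p is monotone in extent", {
  mesh <- fixture_mesh(3)
  sm <- fixture_smoother(3, 18)
  set.seed(8)
  y <- smooth_null_maps(40, mesh, sm)
  resels <- estimate_resels(mesh, y, 39)
  # synthetic cluster table with increasing extents at fixed threshold
  tstar <- qt(1 - 0.001, 39)
  nv <- nrow(mesh$vertices)
  d <- mesh_geodesic(mesh, 20)
  ps <- vapply(c(5, 10, 20, 30), function(rad) {
    vals <- pmax(0, (tstar + 1) * (1 - d / rad) * 2)
    smap <- structure(list(values = vals, kind = "t", term = "x", dof = 39),
                      class = "statmap")
    tab <- find_clusters(smap, mesh, primary_p = 0.001, sign = "positive")
    tab <- rft_cluster_pvalues(tab, resels, mesh)
    tab$p_corrected[1]
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  # degenerate zero extent
  tab0 <- tibble::tibble(cluster_id = 1L, term = "x", sign = "positive",
                         n_vertices = 1L, vertices = list(integer(0)),
                         peak_t = tstar + 0.01, peak_vertex = 1L,
                         area_mm2 = 0, resel_extent = NA_real_,
                         p_corrected = NA_real_)
  attr(tab0, "alpha") <- 0.05
  out <- rft_cluster_pvalues(tab0, resels, mesh, dof = 39, primary_p = 0.001)
  expect_gte(out$p_corrected[1], 0.99)
})

test_that("corrected p decreases with peak height via the primary threshold extent", {
  # higher peaks of the same blob shape have larger supra-threshold extent
  mesh <- fixture_mesh(3)
  sm <- fixture_smoother(3, 18)
  set.seed(9)
  resels <- estimate_resels(mesh, smooth_null_maps(40, mesh, sm), 39)
  d <- mesh_geodesic(mesh, 20)
  ps <- vapply(c(4, 5, 6, 8), function(peak) {
    vals <- pmax(0, peak * (1 - d / 25))
    smap <- structure(list(values = vals, kind = "t", term = "x", dof = 39),
                      class = "statmap")
    tab <- find_clusters(smap, mesh, primary_p = 0.001, sign = "positive")
    rft_cluster_pvalues(tab, resels, mesh)$p_corrected[1]
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})
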