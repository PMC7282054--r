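# lazily built, memoised meshes shared across test files
.fixtures <- new.env(parent = emptyenv())

fixture_mesh <- function(subdiv = 2, regions = 4) {
  key <- paste0("mesh_", subdiv, "_", regions)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_toy_mesh(subdiv, radius_mm = 80,
                                      n_regions_per_hemisphere = regions)
  }
  .fixtures[[key]]
}

fixture_smoother <- function(subdiv, fwhm, regions = 4) {
  key <- paste0("sm_", subdiv, "_", fwhm, "_", regions)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- smoothing_operator(fixture_mesh(subdiv, regions), fwhm)
  }
  .fixtures[[key]]
}

# 4-subject toy cohort, one subject per 2x2 cell
toy_cell_cohort <- function() {
  tibble::tibble(
    subject_id = paste0("s", 1:4),
    group = factor(c("TD", "ASD", "22q11.nonASD", "22q11.ASD"),
                   levels = c("22q11.nonASD", "22q11.ASD", "ASD", "TD")),
    del22q11 = c(0L, 0L, 1L, 1L),
    asd = c(0L, 1L, 0L, 1L)
  )
}

# smooth gaussian subject maps with unit marginal variance
smooth_null_maps <- function(n, mesh, smoother) {
  shrink <- sqrt(Matrix::rowSums(smoother^2))
  y <- matrix(stats::rnorm(n * nrow(mesh$vertices)), n) %*% Matrix::t(smoother)
  sweep(as.matrix(y), 2, shrink, "/")
}
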