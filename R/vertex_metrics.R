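#' Specify a planted spatial effect
#'
#' Ground truth for cluster-detection tests: an effect of `amplitude`
#' (metric units) at `seed_vertex`, tapering linearly to zero at geodesic
#' distance `geodesic_radius` (Dijkstra over edge lengths). `term`
#' determines which subjects receive it: deletion carriers (`"del22q11"`),
#' ASD subjects (`"asd"`), or the 22q11.2DS-and-ASD cell only
#' (`"interaction"`, so the 2x2 cell-mean interaction contrast at the seed
#' equals `amplitude`).
#'
#' @param term One of `"del22q11"`, `"asd"`, `"interaction"`.
#' @param seed_vertex Vertex index on the mesh.
#' @param geodesic_radius Taper radius, mm (> 0).
#' @param amplitude Effect size in the target metric's units.
#' @param metric Target metric: `"CV"`, `"SA"` or `"CT"`.
#' @param plateau Fraction of the radius held at full amplitude before the
#'   linear taper begins (0 = cone; 0.5 = flat core out to half the
#'   radius, mimicking a spatially extended lesion-like effect).
#' @export
planted_effect <- function(term, seed_vertex, geodesic_radius, amplitude,
                           metric = "CT", plateau = 0) {
  stopifnot(term %in% c("del22q11", "asd", "interaction"),
            geodesic_radius > 0, is.finite(amplitude),
            metric %in% c("CV", "SA", "CT"),
            plateau >= 0, plateau < 1)
  structure(list(term = term, seed_vertex = as.integer(seed_vertex),
                 geodesic_radius = geodesic_radius, amplitude = amplitude,
                 metric = metric, plateau = plateau),
            class = "planted_effect")
}

effect_carrier_mask <- function(effect, cohort) {
  switch(effect$term,
         del22q11 = cohort$del22q11 == 1,
         asd = cohort$asd == 1,
         interaction = cohort$del22q11 == 1 & cohort$asd == 1)
}

#' Simulate per-vertex morphometric maps
#'
#' Generates subjects x vertices maps for cortical volume (CV, mm^3 vertex
#' share), surface area (SA, mm^2) and thickness (CT, mm). Each map is a
#' per-subject baseline derived from the subject's global measure (so
#' total-brain covariate structure is present by construction), plus
#' configured covariate slopes on mean-centred covariates, plus planted
#' group/interaction effects tapering to zero at their geodesic radius,
#' plus spatially correlated Gaussian noise (white noise smoothed to
#' `noise_fwhm_mm`, then rescaled so its marginal SD equals `noise_sd`).
#'
#' @param cohort A [simulate_cohort()] tibble.
#' @param mesh A [make_toy_mesh()] object.
#' @param effects List of [planted_effect()] specs.
#' @param covariate_slopes Named list per metric of named slope vectors on
#'   mean-centred cohort columns, e.g. `list(CT = c(age = -0.01))`.
#' @param noise_fwhm_mm Spatial correlation scale of the noise.
#' @param noise_sd Named per-metric marginal noise SD in metric units
#'   (single number recycled).
#' @param seed Integer seed.
#' @return A list with one subjects x vertices matrix per metric (`CV`,
#'   `SA`, `CT`), and attribute `effect_masks`: per effect, the logical
#'   vertex mask where the planted taper is positive.
#' @export
simulate_vertex_metrics <- function(cohort, mesh, effects = list(),
                                    covariate_slopes = list(),
                                    noise_fwhm_mm = 10, noise_sd = c(
                                      CV = 30, SA = 8, CT = 0.25),
                                    seed = 1) {
  nv <- nrow(mesh$vertices)
  n <- nrow(cohort)
  if (length(noise_sd) == 1) {
    noise_sd <- stats::setNames(rep(noise_sd, 3), c("CV", "SA", "CT"))
  }
  if (any(noise_sd < 0)) stop("negative noise_sd")
  for (e in effects) {
    if (e$seed_vertex < 1 || e$seed_vertex > nv) {
      stop("planted seed_vertex out of range: ", e$seed_vertex)
    }
  }
  set.seed(seed)
  total_area <- sum(mesh$vertex_areas)
  # baselines: SA = subject total SA spread over vertex area shares;
  # CT = subject mean CT; CV = area share x thickness
  base <- list(
    SA = outer(cohort$total_sa * 1e6, mesh$vertex_areas / total_area),
    CT = matrix(cohort$mean_ct, n, nv),
    CV = outer(cohort$total_cv * 1e9 / total_area, mesh$vertex_areas)
  )

  smoother <- if (noise_fwhm_mm > 0) smoothing_operator(mesh, noise_fwhm_mm)
  # marginal variance of smoothed unit white noise, per vertex
  shrink <- if (is.null(smoother)) rep(1, nv) else Matrix::rowSums(smoother^2)

  masks <- list()
  taper <- list()
  for (i in seq_along(effects)) {
    e <- effects[[i]]
    d <- mesh_geodesic(mesh, e$seed_vertex)
    pl <- e$plateau %||% 0
    tp <- pmin(1, pmax(0, (1 - d / e$geodesic_radius) / (1 - pl)))
    masks[[i]] <- tp > 0
    taper[[i]] <- tp
  }

  out <- purrr::map(c(CV = "CV", SA = "SA", CT = "CT"), function(m) {
    y <- base[[m]]
    slopes <- covariate_slopes[[m]]
    for (cv in names(slopes)) {
      x <- cohort[[cv]] - mean(cohort[[cv]])
      y <- y + outer(x * slopes[[cv]], rep(1, nv))
    }
    for (i in seq_along(effects)) {
      e <- effects[[i]]
      if (e$metric != m) next
      who <- effect_carrier_mask(e, cohort)
      y[who, ] <- y[who, ] + rep(e$amplitude * taper[[i]],
                                 each = sum(who))
    }
    if (noise_sd[[m]] > 0) {
      eps <- matrix(stats::rnorm(n * nv), n, nv)
      if (!is.null(smoother)) {
        eps <- as.matrix(eps %*% Matrix::t(smoother))
        eps <- sweep(eps, 2, sqrt(shrink), "/")
      }
      y <- y + noise_sd[[m]] * eps
    }
    if (m == "CT") y[y <= 0] <- 1e-3
    y
  })
  attr(out, "effect_masks") <- masks
  attr(out, "mesh_ref") <- "toy_mesh"
  out
}
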