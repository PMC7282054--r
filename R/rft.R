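#' Estimate smoothness (resels) from residual fields
#'
#' Non-isotropic smoothness estimation in the Worsley style: the residual
#' vector at each vertex (across subjects) is scaled to unit norm; for each
#' mesh edge the sum of squared differences of these normalised residuals
#' equals `2 (1 - r)` with `r` the inter-vertex residual correlation, which
#' for a locally Gaussian autocorrelation gives the gradient variance per
#' unit distance `lambda = sum((u_a - u_b)^2) / d^2` and a local
#' `FWHM = sqrt(4 log 2 / lambda)`. Each triangle's resel density is
#' `area / FWHM^2`, i.e. `area * lambda / (4 log 2)` with `lambda` averaged
#' over its three edges.
#'
#' @param mesh A [make_toy_mesh()] object.
#' @param residuals Subjects x vertices residual matrix (>= 3 rows).
#' @param dof Residual degrees of freedom of the fit.
#' @return An object of class `resel_field`: tibble `per_triangle`
#'   (`triangle`, `resels`, `local_fwhm`) plus attributes `total_resels`,
#'   `dof`, `total_area`.
#' @export
estimate_resels <- function(mesh, residuals, dof) {
  stopifnot(is.matrix(residuals), nrow(residuals) >= 3, dof >= 1,
            ncol(residuals) == nrow(mesh$vertices))
  if (qr(residuals)$rank < 2) {
    stop("residual matrix has rank < 2; smoothness is not estimable")
  }
  norms <- sqrt(colSums(residuals^2))
  zero <- norms <= 0
  norms[zero] <- 1
  u <- sweep(residuals, 2, norms, "/")

  e1 <- mesh$edges[, 1]; e2 <- mesh$edges[, 2]
  ssq <- colSums((u[, e1, drop = FALSE] - u[, e2, drop = FALSE])^2)
  lambda_edge <- ssq / mesh$edge_lengths^2
  bad_edge <- zero[e1] | zero[e2]
  lambda_edge[bad_edge] <- NA_real_
  if (any(bad_edge)) {
    message(sum(zero), " zero-variance vertices; their edges take ",
            "neighbouring smoothness estimates")
  }

  edge_key <- paste(pmin(e1, e2), pmax(e1, e2))
  edge_id <- stats::setNames(seq_along(edge_key), edge_key)
  tri <- mesh$triangles
  tri_edges <- cbind(
    edge_id[paste(pmin(tri[, 1], tri[, 2]), pmax(tri[, 1], tri[, 2]))],
    edge_id[paste(pmin(tri[, 2], tri[, 3]), pmax(tri[, 2], tri[, 3]))],
    edge_id[paste(pmin(tri[, 3], tri[, 1]), pmax(tri[, 3], tri[, 1]))]
  )
  lambda_tri <- rowMeans(matrix(lambda_edge[tri_edges], ncol = 3),
                         na.rm = TRUE)
  lambda_tri[!is.finite(lambda_tri)] <- mean(lambda_edge, na.rm = TRUE)
  local_fwhm <- sqrt(4 * log(2) / lambda_tri)
  resels <- mesh$triangle_areas * lambda_tri / (4 * log(2))

  structure(
    list(per_triangle = tibble::tibble(
      triangle = seq_len(nrow(tri)), resels = resels,
      local_fwhm = local_fwhm)),
    total_resels = sum(resels), dof = dof,
    total_area = sum(mesh$triangle_areas),
    class = "resel_field")
}

#' @export
print.resel_field <- function(x, ...) {
  cat("<resel_field> total resels ", round(attr(x, "total_resels"), 1),
      " over ", nrow(x$per_triangle), " triangles (median local FWHM ",
      round(stats::median(x$per_triangle$local_fwhm), 2), " mm, dof ",
      attr(x, "dof"), ")\n", sep = "")
  invisible(x)
}

# per-vertex resel share: one third of each incident triangle's resels
vertex_resels <- function(mesh, resels) {
  nv <- nrow(mesh$vertices)
  out <- rep(0, nv)
  r3 <- resels$per_triangle$resels / 3
  for (j in 1:3) {
    contrib <- tapply(r3, mesh$triangles[, j], sum)
    out[as.integer(names(contrib))] <-
      out[as.integer(names(contrib))] + contrib
  }
  out
}

# fraction of each triangle's area above threshold under linear
# interpolation of the vertex values
triangle_supra_fraction <- function(vals_tri, u) {
  above <- vals_tri > u
  m <- rowSums(above)
  frac <- as.numeric(m == 3)
  one <- which(m == 1)
  if (length(one)) {
    frac[one] <- vapply(one, function(i) {
      v <- vals_tri[i, ]
      a <- v[v > u]; rest <- v[v <= u]
      (a - u)^2 / ((a - rest[1]) * (a - rest[2]))
    }, numeric(1))
  }
  two <- which(m == 2)
  if (length(two)) {
    frac[two] <- vapply(two, function(i) {
      v <- vals_tri[i, ]
      b <- v[v <= u]; rest <- v[v > u]
      1 - (u - b)^2 / ((rest[1] - b) * (rest[2] - b))
    }, numeric(1))
  }
  frac
}

# resel extent of each cluster: linearly interpolated excursion area of
# the thresholded field, in resel units (vertex-share counting would
# overstate boundary extents)
cluster_resel_extents <- function(clusters, resels, mesh, tstar) {
  tri <- mesh$triangles
  nv <- nrow(mesh$vertices)
  cluster_of <- rep(0L, nv)
  sgn <- rep(1, nv)
  for (i in seq_len(nrow(clusters))) {
    cluster_of[clusters$vertices[[i]]] <- clusters$cluster_id[i]
    sgn[clusters$vertices[[i]]] <- if (clusters$sign[i] == "negative") -1 else 1
  }
  out <- stats::setNames(rep(0, nrow(clusters)),
                         as.character(clusters$cluster_id))
  tri_cl <- cbind(cluster_of[tri[, 1]], cluster_of[tri[, 2]],
                  cluster_of[tri[, 3]])
  touched <- which(rowSums(tri_cl > 0) > 0)
  if (length(touched) == 0) return(unname(out))
  vals <- attr(clusters, "map_values")
  for (ti in touched) {
    ids <- unique(tri_cl[ti, tri_cl[ti, ] > 0])
    for (id in ids) {
      verts <- tri[ti, ]
      s <- sgn[verts[cluster_of[verts] == id][1]]
      v <- s * vals[verts]
      # vertices of another (opposite-sign) cluster never count as supra
      v[cluster_of[verts] != id & cluster_of[verts] != 0L] <- -Inf
      frac <- triangle_supra_fraction(rbind(v), tstar)
      out[as.character(id)] <- out[as.character(id)] +
        frac * resels$per_triangle$resels[ti]
    }
  }
  unname(out)
}

#' Find supra-threshold clusters of a t map
#'
#' Thresholds the map at `t* = qt(1 - primary_p, dof)` (positive tail) and
#' at `-t*` (negative tail), and extracts connected components on the mesh
#' adjacency graph separately per sign; opposite-sign clusters are never
#' merged.
#'
#' @param statmap A `statmap` of kind `"t"` (needs `dof`).
#' @param mesh The mesh the map lives on.
#' @param primary_p Cluster-forming threshold, per tail (default 0.001).
#' @param sign `"positive"`, `"negative"` or `"both"`.
#' @param alpha Cluster significance level recorded in the table (two-tailed,
#'   each tail tested at `alpha / 2`).
#' @return A `cluster_table`: tibble with `cluster_id`, `term`, `sign`,
#'   `n_vertices`, `vertices` (list column), `peak_t`, `peak_vertex`,
#'   `area_mm2`, `resel_extent` (`NA` until [rft_cluster_pvalues()]),
#'   `p_corrected` (`NA`), with attributes `primary_threshold`, `primary_p`,
#'   `alpha`, `dof`, `term`.
#' @export
find_clusters <- function(statmap, mesh, primary_p = 0.001,
                          sign = c("both", "positive", "negative"),
                          alpha = 0.05) {
  sign <- match.arg(sign)
  stopifnot(primary_p > 0, primary_p < 1)
  if (is.null(statmap$dof) || !is.finite(statmap$dof)) {
    stop("statmap has no dof; cannot set the primary threshold")
  }
  tstar <- stats::qt(1 - primary_p, statmap$dof)
  g <- mesh_graph(mesh, weighted = FALSE)
  rows <- list()
  for (s in if (sign == "both") c("positive", "negative") else sign) {
    vals <- if (s == "positive") statmap$values else -statmap$values
    above <- which(vals > tstar & is.finite(vals))
    if (length(above) == 0) next
    comp <- igraph::components(igraph::induced_subgraph(g, above))
    for (ci in seq_len(comp$no)) {
      members <- above[comp$membership == ci]
      peak <- members[which.max(vals[members])]
      rows[[length(rows) + 1]] <- tibble::tibble(
        sign = s, n_vertices = length(members), vertices = list(members),
        peak_t = statmap$values[peak], peak_vertex = peak,
        area_mm2 = sum(mesh$vertex_areas[members]))
    }
  }
  tab <- if (length(rows) == 0) {
    tibble::tibble(sign = character(), n_vertices = integer(),
                   vertices = list(), peak_t = numeric(),
                   peak_vertex = integer(), area_mm2 = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  tab <- tab |>
    dplyr::mutate(cluster_id = dplyr::row_number(),
                  term = statmap$term %||% NA_character_,
                  resel_extent = NA_real_, p_corrected = NA_real_) |>
    dplyr::relocate("cluster_id", "term")
  structure(tab, primary_threshold = tstar, primary_p = primary_p,
            alpha = alpha, dof = statmap$dof, term = statmap$term,
            map_values = statmap$values,
            class = c("cluster_table", class(tab)))
}

# 2-D Euler characteristic density of a t field, resel units (4 log 2
# folded in, Worsley-style)
ec_density_t2 <- function(t, dof) {
  (4 * log(2)) / (2 * pi)^(3 / 2) *
    exp(lgamma((dof + 1) / 2) - lgamma(dof / 2)) / sqrt(dof / 2) *
    t * (1 + t^2 / dof)^(-(dof - 1) / 2)
}

#' RFT cluster-corrected p-values
#'
#' Assigns each cluster a family-wise corrected p-value from the standard
#' random-field cluster-extent result for t fields on a 2-D surface:
#' the expected cluster count above the primary threshold is
#' `E[m] = R * rho_2(t*)` (with `R` the total resels and `rho_2` the 2-D
#' Euler characteristic density), the expected supra-threshold resel mass
#' is `E[n] = R * P(T > t*)`, and the cluster resel extent has an
#' exponential tail `P(K >= k) = exp(-k E[m] / E[n])` (the `D = 2` case of
#' the `k^(2/D)` form). Then
#' `p = 1 - exp(-E[m] * P(K >= k))`. Using resel extent rather than mm^2
#' is what keeps the correction valid for non-isotropic fields; mm^2 is
#' reported for interpretability. Clusters with zero resel extent get
#' `p = 1`.
#'
#' @param clusters A [find_clusters()] table.
#' @param resels An [estimate_resels()] field (same mesh).
#' @param mesh The mesh (for the per-vertex resel shares).
#' @param dof Residual dof (defaults to the value recorded on `clusters`).
#' @param primary_p Per-tail primary threshold probability (defaults to the
#'   recorded value).
#' @return The cluster table with `resel_extent` and `p_corrected` filled,
#'   sorted by `p_corrected` then descending extent, plus a `significant`
#'   flag at the recorded two-tailed `alpha` (each tail at `alpha / 2`).
#' @export
rft_cluster_pvalues <- function(clusters, resels, mesh,
                                dof = attr(clusters, "dof"),
                                primary_p = attr(clusters, "primary_p")) {
  total <- attr(resels, "total_resels")
  if (is.null(total) || total <= 0) stop("total_resels must be positive")
  alpha <- attr(clusters, "alpha") %||% 0.05
  if (nrow(clusters) == 0) return(clusters)
  tstar <- stats::qt(1 - primary_p, dof)
  em <- total * ec_density_t2(tstar, dof)
  en <- total * stats::pt(tstar, dof, lower.tail = FALSE)
  beta <- em / en
  k <- if (!is.null(attr(clusters, "map_values"))) {
    cluster_resel_extents(clusters, resels, mesh, tstar)
  } else {
    vres <- vertex_resels(mesh, resels)
    vapply(clusters$vertices, function(v) sum(vres[v]), numeric(1))
  }
  p <- ifelse(k <= 0, 1, pmin(1, 1 - exp(-em * exp(-beta * k))))
  out <- clusters |>
    dplyr::mutate(resel_extent = k, p_corrected = p,
                  significant = p < alpha / 2) |>
    dplyr::arrange(.data$p_corrected, dplyr::desc(.data$resel_extent)) |>
    dplyr::mutate(cluster_id = dplyr::row_number())
  attrs <- attributes(clusters)
  for (a in c("primary_threshold", "primary_p", "alpha", "dof", "term")) {
    attr(out, a) <- attrs[[a]]
  }
  class(out) <- class(clusters)
  out
}
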