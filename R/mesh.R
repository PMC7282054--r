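#' Build a two-hemisphere toy cortical surface
#'
#' Constructs a subdivided icosahedral sphere as a stand-in for a
#' reconstructed cortical surface. The sphere is split into a left and a
#' right hemisphere at the x = 0 plane and each hemisphere is partitioned
#' into `n_regions_per_hemisphere` contiguous parcels of near-equal vertex
#' count (a graph-Voronoi parcellation grown from farthest-point-sampled
#' seeds). Random-field-theory cluster inference and regional aggregation
#' depend only on mesh topology and metric, so a sphere is a valid test
#' domain even though it is not brain-shaped.
#'
#' @param n_subdivisions Number of 4-to-1 triangle subdivisions of the base
#'   icosahedron (>= 1). Vertex count is `10 * 4^n + 2`.
#' @param radius_mm Sphere radius in millimetres. The default 80 mm gives a
#'   total area of the order of a human cortical hemisphere pair.
#' @param n_regions_per_hemisphere Parcels per hemisphere; defaults to 34,
#'   the regional granularity of the Desikan-Killiany atlas.
#'
#' @return An object of class `toy_mesh`: a list with `vertices` (V x 3
#'   matrix, mm), `triangles` (F x 3 integer matrix), `edges` (E x 2),
#'   `edge_lengths` (mm), `vertex_areas` (mm^2, one third of each incident
#'   triangle), `triangle_areas`, `parcellation` (integer region id,
#'   `1 .. 2 * n_regions_per_hemisphere`, left hemisphere first),
#'   `hemisphere` (`"lh"`/`"rh"` per vertex) and `mean_edge_length`.
#' @export
#' @examples
#' mesh <- make_toy_mesh(2, radius_mm = 80, n_regions_per_hemisphere = 4)
#' mesh
make_toy_mesh <- function(n_subdivisions = 3, radius_mm = 80,
                          n_regions_per_hemisphere = 34) {
  stopifnot(n_subdivisions >= 1, radius_mm > 0, n_regions_per_hemisphere >= 1)
  ico <- icosphere(n_subdivisions, radius_mm)
  v <- ico$vertices
  tri <- ico$triangles

  edges <- triangles_to_edges(tri)
  edge_lengths <- sqrt(rowSums((v[edges[, 1], , drop = FALSE] -
                                  v[edges[, 2], , drop = FALSE])^2))
  tri_areas <- triangle_areas(v, tri)
  vertex_areas <- rep(0, nrow(v))
  for (j in 1:3) {
    contrib <- tapply(tri_areas / 3, tri[, j], sum)
    vertex_areas[as.integer(names(contrib))] <-
      vertex_areas[as.integer(names(contrib))] + contrib
  }

  hemisphere <- ifelse(v[, 1] < 0, "lh", "rh")
  parcellation <- integer(nrow(v))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- edge_lengths
  offset <- 0L
  for (h in c("lh", "rh")) {
    idx <- which(hemisphere == h)
    if (length(idx) < n_regions_per_hemisphere) {
      stop("n_regions_per_hemisphere (", n_regions_per_hemisphere,
           ") exceeds the ", h, " hemisphere vertex count (", length(idx), ")")
    }
    sub <- igraph::induced_subgraph(g, idx)
    labels <- grow_regions(sub, n_regions_per_hemisphere)
    parcellation[idx] <- labels + offset
    offset <- offset + n_regions_per_hemisphere
  }

  structure(list(
    vertices = v, triangles = tri, edges = edges,
    edge_lengths = edge_lengths, triangle_areas = tri_areas,
    vertex_areas = vertex_areas, parcellation = parcellation,
    hemisphere = hemisphere, radius_mm = radius_mm,
    n_regions_per_hemisphere = n_regions_per_hemisphere,
    mean_edge_length = mean(edge_lengths)
  ), class = "toy_mesh")
}

#' @export
print.toy_mesh <- function(x, ...) {
  cat("<toy_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$triangles),
      " triangles, ", nrow(x$edges), " edges\n", sep = "")
  cat("  radius ", x$radius_mm, " mm, total area ",
      round(sum(x$triangle_areas)), " mm^2, mean edge ",
      round(x$mean_edge_length, 2), " mm\n", sep = "")
  cat("  parcellation: ", x$n_regions_per_hemisphere,
      " regions per hemisphere\n", sep = "")
  invisible(x)
}

# base icosahedron subdivided n times, projected to the sphere
icosphere <- function(n_subdivisions, radius) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  tri <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(n_subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    new_v <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      new_v <<- rbind(new_v, (v[a, ] + v[b, ]) / 2)
      id <- nrow(new_v)
      midpoint_cache[[key]] <- id
      id
    }
    new_tri <- matrix(0L, nrow(tri) * 4, 3)
    for (f in seq_len(nrow(tri))) {
      a <- tri[f, 1]; b <- tri[f, 2]; cc <- tri[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      new_tri[(f - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- new_v
    tri <- new_tri
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  storage.mode(tri) <- "integer"
  list(vertices = v, triangles = tri)
}

triangles_to_edges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  storage.mode(e) <- "integer"
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

triangle_areas <- function(v, tri) {
  a <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sqrt(rowSums(cr^2)) / 2
}

# deterministic farthest-point seeds + round-robin BFS growth; every region
# is connected by construction and sizes are near-equal
grow_regions <- function(g, k) {
  n <- igraph::vcount(g)
  d1 <- igraph::distances(g, v = 1)[1, ]
  seeds <- which.max(d1)
  while (length(seeds) < k) {
    d <- igraph::distances(g, v = seeds)
    dmin <- apply(d, 2, min)
    dmin[seeds] <- -1
    seeds <- c(seeds, which.max(dmin))
  }
  labels <- integer(n)
  labels[seeds] <- seq_len(k)
  queues <- lapply(seeds, function(s) s)
  adj <- igraph::as_adj_list(g)
  remaining <- n - k
  while (remaining > 0) {
    for (r in seq_len(k)) {
      q <- queues[[r]]
      while (length(q) > 0) {
        head <- q[[1]]
        nb <- adj[[head]]
        free <- nb[labels[nb] == 0L]
        if (length(free) > 0) {
          pick <- free[1]
          labels[pick] <- r
          remaining <- remaining - 1
          queues[[r]] <- c(q, pick)
          break
        }
        q <- q[-1]
        queues[[r]] <- q
      }
      if (remaining == 0) break
    }
  }
  labels
}

#' Mesh vertex adjacency graph
#'
#' @param mesh A [make_toy_mesh()] object.
#' @param weighted Use edge lengths (mm) as weights.
#' @return An igraph graph on the mesh vertices.
#' @export
mesh_graph <- function(mesh, weighted = TRUE) {
  g <- igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
  if (weighted) igraph::E(g)$weight <- mesh$edge_lengths
  g
}

#' Geodesic distances from a seed vertex
#'
#' Dijkstra shortest paths over mesh edge lengths: an adequate geodesic
#' approximation for planting and measuring spatial effects on a fine mesh.
#'
#' @inheritParams mesh_graph
#' @param from Seed vertex index.
#' @return Numeric vector of distances (mm) to every vertex.
#' @export
mesh_geodesic <- function(mesh, from) {
  stopifnot(from >= 1, from <= nrow(mesh$vertices))
  as.numeric(igraph::distances(mesh_graph(mesh), v = from))
}

#' Summarise a mesh parcellation as a tibble
#'
#' @inheritParams mesh_graph
#' @return A tibble with one row per region: `region`, `hemisphere`,
#'   `n_vertices`, `area_mm2`.
#' @export
tidy_parcellation <- function(mesh) {
  tibble::tibble(
    region = mesh$parcellation,
    hemisphere = mesh$hemisphere,
    area = mesh$vertex_areas
  ) |>
    dplyr::group_by(.data$region, .data$hemisphere) |>
    dplyr::summarise(n_vertices = dplyr::n(), area_mm2 = sum(.data$area),
                     .groups = "drop") |>
    dplyr::arrange(.data$region)
}
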