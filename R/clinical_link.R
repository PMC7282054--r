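#' Specify a planted low-rank brain-behaviour link
#'
#' Ground truth for CCA parameter-recovery tests: `n_components` latent
#' dimensions, each pairing a brain-side projection with a clinical-side
#' projection at target canonical correlation `canonical_rhos[k]`.
#'
#' @param canonical_rhos Strictly decreasing target correlations in (0, 1).
#' @param brain_weights Components x p matrix of brain-side weights (rows
#'   are orthonormalised internally).
#' @param clinical_weights Components x q matrix of clinical-side weights.
#' @param noise_sd Residual SD added to the clinical matrix, in units of
#'   the (unit-variance) latent scores.
#' @export
latent_link <- function(canonical_rhos, brain_weights, clinical_weights,
                        noise_sd = 0.2) {
  stopifnot(all(canonical_rhos > 0), all(canonical_rhos < 1))
  if (length(canonical_rhos) > 1 && any(diff(canonical_rhos) >= 0)) {
    stop("canonical_rhos must be strictly decreasing")
  }
  brain_weights <- rbind(brain_weights)
  clinical_weights <- rbind(clinical_weights)
  stopifnot(nrow(brain_weights) == length(canonical_rhos),
            nrow(clinical_weights) == length(canonical_rhos),
            ncol(clinical_weights) >= 1)
  if (any(rowSums(brain_weights^2) == 0) ||
      any(rowSums(clinical_weights^2) == 0)) {
    stop("weight rows must be non-zero")
  }
  structure(list(n_components = length(canonical_rhos),
                 canonical_rhos = canonical_rhos,
                 brain_weights = brain_weights,
                 clinical_weights = clinical_weights,
                 noise_sd = noise_sd),
            class = "latent_link")
}

orthonormal_rows <- function(w) {
  qr_w <- qr(t(w))
  t(qr.Q(qr_w)[, seq_len(nrow(w)), drop = FALSE]) *
    sign(diag(qr.R(qr_w)))[seq_len(nrow(w))]
}

#' Draw clinical scores carrying a planted canonical structure
#'
#' For each component `k`, the brain projection `u_k` of the (standardized)
#' feature matrix onto the k-th brain weight row is paired with a clinical
#' latent `v_k = rho_k u_k + sqrt(1 - rho_k^2) e_k`, so
#' `cor(u_k, v_k) = rho_k` in expectation. The clinical matrix is
#' `V C + noise_sd * E` with `C` the orthonormalised clinical weight rows.
#'
#' @param x Subjects x p feature matrix (or `region_features` tibble).
#' @param link A [latent_link()] spec.
#' @param seed Integer seed.
#' @return Subjects x q matrix of unit-scale clinical scores, with
#'   attributes `latent_u` and `latent_v` (subjects x components) holding
#'   the planted projections.
#' @export
simulate_latent_scores <- function(x, link, seed = 1) {
  if (inherits(x, "region_features")) x <- feature_matrix(x)
  x <- as.matrix(x)
  set.seed(seed)
  n <- nrow(x)
  stopifnot(ncol(x) == ncol(link$brain_weights))
  bw <- orthonormal_rows(link$brain_weights)
  cw <- orthonormal_rows(link$clinical_weights)
  u <- scale(x %*% t(bw))
  v <- matrix(0, n, link$n_components)
  for (k in seq_len(link$n_components)) {
    rho <- link$canonical_rhos[k]
    v[, k] <- rho * u[, k] + sqrt(1 - rho^2) * stats::rnorm(n)
  }
  q <- ncol(cw)
  y <- v %*% cw + link$noise_sd * matrix(stats::rnorm(n * q), n, q)
  attr(y, "latent_u") <- u
  attr(y, "latent_v") <- v
  y
}

#' Update a cohort's SRS subdomains with a planted brain-behaviour link
#'
#' Replaces the cohort's SRS subdomain scores with scores generated by
#' [simulate_latent_scores()] from the supplied regional features, mapped
#' to the SRS scale: group-specific subdomain offsets (by default the
#' group SRS totals of the study's demographic table split proportionally
#' across subdomains, keeping the latent link the only brain-behaviour
#' structure) plus `srs_scale` times the unit-scale linked scores,
#' truncated at zero.
#'
#' @param cohort A [simulate_cohort()] tibble.
#' @param region_features Subjects x p matrix or `region_features` tibble,
#'   row-matched to the cohort.
#' @param link A [latent_link()] spec.
#' @param srs_scale SRS points per unit latent score (default 10).
#' @param group_offsets Optional 4 x 5 matrix of group x subdomain mean
#'   offsets; defaults to the configured group SRS means.
#' @param config The [cohort_config()] supplying default offsets.
#' @param seed Integer seed.
#' @return The cohort with `srs_*` and `srs_total` columns replaced, and
#'   attributes `latent_u` / `latent_v` carrying the planted projections.
#' @export
simulate_clinical_scores <- function(cohort, region_features, link,
                                     srs_scale = 10, group_offsets = NULL,
                                     config = cohort_config(), seed = 1) {
  x <- if (inherits(region_features, "region_features")) {
    feature_matrix(region_features)
  } else {
    as.matrix(region_features)
  }
  if (nrow(x) != nrow(cohort)) stop("row counts of cohort and features differ")
  y <- simulate_latent_scores(x, link, seed)
  if (ncol(y) != 5) stop("clinical_weights must have 5 columns for SRS")
  if (is.null(group_offsets)) {
    group_offsets <- outer(config$srs_total$mean, config$srs_split)
    rownames(group_offsets) <- group_levels()
  }
  gi <- as.integer(cohort$group)
  srs <- group_offsets[gi, , drop = FALSE] + srs_scale * y
  srs <- pmax(srs, 0)
  colnames(srs) <- paste0("srs_", srs_domains())
  out <- cohort
  out[, colnames(srs)] <- tibble::as_tibble(as.data.frame(srs))
  out$srs_total <- rowSums(srs)
  attr(out, "latent_u") <- attr(y, "latent_u")
  attr(out, "latent_v") <- attr(y, "latent_v")
  out
}

#' Simulate two groups with divergent neuroanatomical loading structure
#'
#' Ground truth for the congruence comparison: both groups share the same
#' clinical-side structure (the same latent-to-SRS weight rows and the same
#' canonical strengths), but the latent components express through
#' orthogonal (disjoint-support) brain patterns in the two groups.
#' Features are generated as `X_g = pattern_scale * T_g B_g + sigma_x E`
#' with `B_g` group-specific pattern rows concentrated on disjoint feature
#' blocks (carriers: the first `s` features; non-carriers: the next `s`)
#' and `T_g` unit-variance latents, and clinical scores as
#' `Y_g = (T_g diag(rho) + sqrt(1 - rho^2) N) C + noise_sd E`. A
#' full-sample CCA on the stacked data then recovers compromise variates
#' whose clinical loadings agree across groups while the group-specific
#' brain loadings diverge. `pattern_scale` controls how strongly the
#' pattern dominates per-feature noise (and hence how far the group
#' loadings separate).
#'
#' @param n_per_group Subjects per group (carriers first).
#' @param p Number of brain features.
#' @param q Number of clinical variables.
#' @param rhos Latent canonical strengths (length s).
#' @param pattern_scale Amplitude of the group pattern relative to the
#'   unit feature noise.
#' @param sigma_x Residual feature noise SD.
#' @param noise_sd Residual clinical noise SD.
#' @param seed Integer seed.
#' @return A list with `x` (2n x p), `y` (2n x q), `carrier_mask`,
#'   `brain_patterns` (list of the two B_g), `clinical_weights`.
#' @export
simulate_group_divergent_data <- function(n_per_group = 200, p = 20, q = 5,
                                          rhos = c(0.8, 0.6),
                                          pattern_scale = 5,
                                          sigma_x = 1, noise_sd = 0.2,
                                          seed = 1) {
  set.seed(seed)
  s <- length(rhos)
  stopifnot(2 * s <= p)
  b1 <- matrix(0, s, p); b2 <- matrix(0, s, p)
  for (k in seq_len(s)) {
    b1[k, k] <- 1
    b2[k, s + k] <- 1
  }
  cw <- orthonormal_rows(matrix(stats::rnorm(s * q), s))
  gen <- function(bg, n) {
    t_lat <- matrix(stats::rnorm(n * s), n)
    x <- pattern_scale * t_lat %*% bg +
      sigma_x * matrix(stats::rnorm(n * p), n)
    v <- sweep(t_lat, 2, rhos, "*") +
      sweep(matrix(stats::rnorm(n * s), n), 2, sqrt(1 - rhos^2), "*")
    y <- v %*% cw + noise_sd * matrix(stats::rnorm(n * q), n)
    list(x = x, y = y)
  }
  g1 <- gen(b1, n_per_group)
  g2 <- gen(b2, n_per_group)
  x <- rbind(g1$x, g2$x)
  colnames(x) <- paste0("f", seq_len(p))
  y <- rbind(g1$y, g2$y)
  colnames(y) <- paste0("y", seq_len(q))
  list(x = x, y = y,
       carrier_mask = rep(c(TRUE, FALSE), each = n_per_group),
       brain_patterns = list(b1, b2), clinical_weights = cw)
}
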