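#' Aggregate vertex maps into regional features
#'
#' Collapses subjects x vertices maps onto the mesh parcellation: cortical
#' thickness becomes the area-weighted regional mean, surface area and
#' volume the regional sums. Feature order is hemisphere x region x metric
#' and names follow `lh_region07_CT`, giving `p = 2 * regions * 3` columns
#' when all three metrics are supplied.
#'
#' @param mesh A [make_toy_mesh()] object carrying the parcellation.
#' @param metrics Named list of subjects x vertices matrices (names among
#'   `CV`, `SA`, `CT`), e.g. the output of [simulate_vertex_metrics()].
#' @return A `region_features` tibble: `subject` index plus one numeric
#'   column per feature, with attributes `residualized = FALSE`,
#'   `standardized = FALSE` and `feature_meta` (tibble of name,
#'   hemisphere, region, metric).
#' @export
aggregate_regions <- function(mesh, metrics) {
  stopifnot(length(metrics) >= 1, !is.null(names(metrics)))
  regions <- sort(unique(mesh$parcellation))
  counts <- tabulate(mesh$parcellation, nbins = max(regions))
  if (any(counts[regions] == 0)) stop("empty region in parcellation")
  nh <- mesh$n_regions_per_hemisphere
  n <- nrow(metrics[[1]])

  meta <- tidyr::expand_grid(
    hemisphere = c("lh", "rh"),
    region = seq_len(nh),
    metric = names(metrics)
  ) |>
    dplyr::mutate(
      global_region = .data$region + ifelse(.data$hemisphere == "lh", 0L, nh),
      name = sprintf("%s_region%02d_%s", .data$hemisphere, .data$region,
                     .data$metric))

  w <- mesh$vertex_areas
  cols <- purrr::pmap(meta, function(hemisphere, region, metric,
                                     global_region, name) {
    idx <- which(mesh$parcellation == global_region)
    m <- metrics[[metric]][, idx, drop = FALSE]
    if (metric == "CT") {
      as.numeric(m %*% w[idx]) / sum(w[idx])
    } else {
      rowSums(m)
    }
  })
  names(cols) <- meta$name
  out <- tibble::as_tibble(cols)
  out <- dplyr::bind_cols(tibble::tibble(subject = seq_len(n)), out)
  attr(out, "feature_meta") <- meta
  attr(out, "residualized") <- FALSE
  attr(out, "standardized") <- FALSE
  class(out) <- c("region_features", class(out))
  out
}

#' Extract the numeric feature matrix
#'
#' @param features A `region_features` tibble.
#' @return Subjects x p numeric matrix with feature column names.
#' @export
feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features), "subject"), drop = FALSE])
}

feature_metric <- function(name) sub(".*_", "", name)

#' Residualize regional features for nuisance covariates
#'
#' Replaces each feature column by its OLS residuals on linear and
#' quadratic age, gender, site, full-scale IQ and the metric-matched
#' total-brain measure, fitted across all subjects (not within groups, so
#' group differences of interest survive). Columns are then standardized to
#' mean 0, SD 1; columns with (near-)zero residual variance are left at
#' zero with a warning.
#'
#' @param features A [aggregate_regions()] tibble, row-matched to `cohort`.
#' @param cohort The cohort tibble providing the nuisance covariates.
#' @return The features tibble with `residualized` and `standardized`
#'   attributes set.
#' @export
residualize_features <- function(features, cohort) {
  x <- feature_matrix(features)
  stopifnot(nrow(x) == nrow(cohort))
  base <- cbind(
    intercept = 1,
    age = cohort$age - mean(cohort$age),
    age2 = cohort$age2 - mean(cohort$age2),
    gender = as.numeric(cohort$gender == levels(cohort$gender)[2]),
    stats::model.matrix(~site, data = cohort)[, -1, drop = FALSE],
    fsiq = cohort$fsiq - mean(cohort$fsiq)
  )
  out <- x
  for (m in unique(feature_metric(colnames(x)))) {
    tb <- cohort[[total_brain_column(m)]]
    nuis <- cbind(base, total_brain = tb - mean(tb))
    if (qr(nuis)$rank < ncol(nuis)) stop("rank-deficient nuisance design")
    cols <- which(feature_metric(colnames(x)) == m)
    out[, cols] <- stats::lm.fit(nuis, x[, cols, drop = FALSE])$residuals
  }
  sds <- apply(out, 2, stats::sd)
  degenerate <- sds < 1e-8
  if (any(degenerate)) {
    warning("zero-variance residual columns left at zero: ",
            paste(colnames(x)[degenerate], collapse = ", "))
    out[, degenerate] <- 0
  }
  ok <- !degenerate
  out[, ok] <- scale(out[, ok, drop = FALSE])
  res <- features
  res[, colnames(x)] <- tibble::as_tibble(as.data.frame(out))
  attr(res, "residualized") <- TRUE
  attr(res, "standardized") <- TRUE
  res
}
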