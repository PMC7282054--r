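#' Default end-to-end pipeline configuration
#'
#' Collects every stage's parameters in one (YAML-serialisable) list:
#' mesh resolution, cohort distributions, planted effects, smoothing,
#' GLM terms, RFT thresholds and CCA options. The defaults are the study
#' conditions the synthetic cohort emulates; problem sizes are kept at a
#' scale where the full pipeline runs in seconds.
#'
#' @param seed Master seed; each stage derives its own sub-seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    mesh = list(n_subdivisions = 3, radius_mm = 80,
                n_regions_per_hemisphere = 34),
    cohort = cohort_config(),
    metrics = list(noise_fwhm_mm = 10,
                   noise_sd = c(CV = 30, SA = 8, CT = 0.25),
                   smoothing_fwhm_mm = 5),
    effects = list(),
    link = NULL,
    glm = list(terms = c("del22q11", "asd", "interaction")),
    rft = list(primary_p = 0.001, alpha = 0.05),
    cca = list(n_permutations = 499, max_features = NULL)
  ), class = "pipeline_config")
}

stage_seed <- function(config, offset) {
  (config$seed * 1000L + offset) %% .Machine$integer.max
}

#' Run the full two-track analysis pipeline
#'
#' Simulates the cohort, mesh and vertex metrics; smooths each metric and
#' fits the factorial vertex GLM; runs RFT cluster correction for every
#' configured term; aggregates regional features, residualizes them,
#' selects features by stepwise AIC and fits the CCA with its full
#' significance report; and compares forward-model loadings between
#' deletion carriers and non-carriers. When `outdir` is given every table
#' is written (TSV/JSON) with the seed and a config hash embedded.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory.
#' @return A `pipeline_result` list with elements `cohort`, `mesh`,
#'   `cluster_tables` (tibble over metric x term), `features`,
#'   `selection`, `cca` (sorted fit), `cca_report`, `comparison`,
#'   `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  hash <- rlang::hash(unclass(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  mesh <- stage("mesh", do.call(make_toy_mesh, config$mesh))
  cohort <- stage("cohort",
                  simulate_cohort(config$cohort, stage_seed(config, 1)))
  metrics <- stage("vertex_metrics", simulate_vertex_metrics(
    cohort, mesh, effects = config$effects,
    noise_fwhm_mm = config$metrics$noise_fwhm_mm,
    noise_sd = config$metrics$noise_sd, seed = stage_seed(config, 2)))

  smoothed <- stage("smoothing", purrr::map(
    metrics, ~smooth_metric(mesh, .x, config$metrics$smoothing_fwhm_mm)))

  cluster_tables <- stage("glm_rft", purrr::imap(smoothed, function(m, name) {
    design <- build_design(cohort, design_spec(metric = name))
    fit <- fit_vertex_glm(design, m)
    resels <- estimate_resels(mesh, fit$residuals, fit$dof)
    purrr::map(config$glm$terms, function(term) {
      tab <- find_clusters(contrast_tmap(fit, term), mesh,
                           primary_p = config$rft$primary_p,
                           alpha = config$rft$alpha)
      tab <- rft_cluster_pvalues(tab, resels, mesh)
      tibble::as_tibble(tab) |>
        dplyr::mutate(metric = name, term = term) |>
        dplyr::select(-"vertices")
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows())

  features <- stage("regions", {
    f <- aggregate_regions(mesh, metrics)
    residualize_features(f, cohort)
  })
  if (!is.null(config$link)) {
    cohort <- stage("clinical_link", simulate_clinical_scores(
      cohort, features, config$link, seed = stage_seed(config, 3)))
  }
  clinical <- as.matrix(cohort[, paste0("srs_", srs_domains())])

  selection <- stage("feature_selection", stepwise_aic_select(
    features, clinical, max_features = config$cca$max_features))
  xsel <- feature_matrix(features)[, selection$selected, drop = FALSE]

  cca <- stage("cca", {
    fit <- fit_cca(xsel, clinical)
    report <- cca_significance(
      fit, xsel, clinical,
      n_permutations = config$cca$n_permutations,
      seed = stage_seed(config, 4))
    sort_variates(fit, report)
  })
  comparison <- stage("group_comparison", compare_groups(
    xsel, clinical, cca$fit, cohort$del22q11 == 1))

  result <- structure(list(
    cohort = cohort, mesh = mesh, cluster_tables = cluster_tables,
    features = features, selection = selection,
    cca = cca$fit, cca_report = cca$report, comparison = comparison,
    seed = config$seed, config_hash = hash
  ), class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(result, outdir, config)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed ", x$seed, ", config ", x$config_hash, "\n",
      sep = "")
  cat("  cohort: ", nrow(x$cohort), " subjects; clusters: ",
      nrow(x$cluster_tables), " (", sum(x$cluster_tables$significant),
      " significant)\n", sep = "")
  cat("  CCA: ", length(x$selection$selected), " features selected, ",
      "leading canonical correlation ", round(x$cca$cor[1], 3), "\n",
      sep = "")
  cat("  mean Tucker phi: brain ", round(x$comparison$mean_phi_x, 3),
      ", clinical ", round(x$comparison$mean_phi_y, 3), "\n", sep = "")
  invisible(x)
}

#' Write a pipeline result bundle
#'
#' TSV for tables, JSON for the CCA model and reports; every file carries
#' the seed and config hash in a metadata JSON.
#'
#' @param result A [run_pipeline()] result.
#' @param outdir Output directory (created if missing).
#' @param config The config used (stored as YAML).
#' @export
write_pipeline_result <- function(result, outdir, config = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = result$seed, config_hash = result$config_hash)
  jsonlite::write_json(meta, file.path(outdir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  }
  readr::write_tsv(result$cohort, file.path(outdir, "cohort.tsv"))
  readr::write_tsv(result$cluster_tables, file.path(outdir, "clusters.tsv"))
  readr::write_tsv(tibble::as_tibble(result$features),
                   file.path(outdir, "features.tsv"))
  readr::write_tsv(result$selection$paths,
                   file.path(outdir, "selection_paths.tsv"))
  readr::write_tsv(result$comparison$tests,
                   file.path(outdir, "loading_differences.tsv"))
  jsonlite::write_json(list(
    weights_x = result$cca$wx, weights_y = result$cca$wy,
    canonical_correlations = result$cca$cor,
    loadings_x = result$cca$loadings_x, loadings_y = result$cca$loadings_y,
    order = result$cca$order, sign_flip = result$cca$sign_flip
  ), file.path(outdir, "cca_model.json"), digits = NA, matrix = "columnmajor")
  jsonlite::write_json(list(
    wilks = result$cca_report$wilks, pillai = result$cca_report$pillai,
    bartlett = result$cca_report$bartlett,
    adequacy = result$cca_report$adequacy,
    total_redundancy = result$cca_report$total_redundancy,
    rv = result$cca_report$rv,
    congruence = result$comparison$congruence,
    mean_phi_x = result$comparison$mean_phi_x,
    mean_phi_y = result$comparison$mean_phi_y
  ), file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "columns")
  invisible(file.path(outdir))
}

#' Write / read a mesh in OFF format
#'
#' @param mesh A [make_toy_mesh()] object.
#' @param path Output path.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$triangles), 0), con)
  utils::write.table(mesh$vertices, con, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
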