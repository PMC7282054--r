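#' Specify the factorial design
#'
#' Encodes the vertex-wise model
#' `Y = b0 + b1 del22q11 + b2 asd + b3 del22q11:asd + b4 gender + b5 site
#'  + b6 fsiq + b7 age + b8 age^2 + b9 total_brain + e`.
#' The two experimental factors use sum-to-zero (+1/2, -1/2) coding so that
#' `b1`/`b2` are main effects averaged over the other factor (carrier vs
#' non-carrier marginal comparisons); gender and site are dummy coded;
#' continuous covariates are mean-centred across groups when `centering` is
#' on. The total-brain covariate is metric-matched: total CV for CV maps,
#' total SA for SA, mean CT for CT.
#'
#' @param interaction Include the del22q11 x asd product column.
#' @param covariates Continuous covariates, in order.
#' @param centering Mean-centre continuous covariates across groups.
#' @param metric Which metric's maps the design will be fitted to
#'   (selects the matched total-brain column).
#' @param factors Experimental factor columns to include (subset analyses
#'   may drop one); gender/site nuisance factors follow
#'   `nuisance_factors`.
#' @param nuisance_factors Include gender and site dummies when present.
#' @export
design_spec <- function(interaction = TRUE,
                        covariates = c("fsiq", "age", "age2", "total_brain"),
                        centering = TRUE, metric = c("CV", "SA", "CT"),
                        factors = c("del22q11", "asd"),
                        nuisance_factors = TRUE) {
  metric <- match.arg(metric)
  structure(list(interaction = interaction, covariates = covariates,
                 centering = centering, metric = metric,
                 factors = factors, nuisance_factors = nuisance_factors),
            class = "design_spec")
}

total_brain_column <- function(metric) {
  switch(metric, CV = "total_cv", SA = "total_sa", CT = "mean_ct")
}

#' Build the design matrix
#'
#' @param cohort A [simulate_cohort()] tibble (or any tibble with the model
#'   columns).
#' @param spec A [design_spec()].
#' @return An object of class `design_matrix`: list with `X` (subjects x p,
#'   named columns), `term_map` (term -> column indices), `rank`, `cohort`
#'   (the factor columns retained for effect-size group counts).
#' @export
build_design <- function(cohort, spec = design_spec()) {
  n <- nrow(cohort)
  cols <- list(intercept = rep(1, n))
  term_map <- list(intercept = 1L)

  code <- function(x) x - 0.5  # 0/1 -> -1/2, +1/2 sum-to-zero
  for (f in spec$factors) cols[[f]] <- code(cohort[[f]])
  if (isTRUE(spec$interaction) &&
      all(c("del22q11", "asd") %in% spec$factors)) {
    cols$interaction <- cols$del22q11 * cols$asd
  }
  if (isTRUE(spec$nuisance_factors) && "gender" %in% names(cohort) &&
      nlevels(droplevels(cohort$gender)) > 1) {
    cols$gender <- as.numeric(cohort$gender == levels(cohort$gender)[2])
  }
  if (isTRUE(spec$nuisance_factors) && "site" %in% names(cohort)) {
    site <- droplevels(cohort$site)
    if (nlevels(site) > 1) {
      for (l in levels(site)[-1]) {
        cols[[paste0("site", match(l, levels(cohort$site)))]] <-
          as.numeric(site == l)
      }
    }
  }
  for (cv in spec$covariates) {
    src <- if (cv == "total_brain") total_brain_column(spec$metric) else cv
    if (!src %in% names(cohort)) stop("missing covariate column: ", src)
    x <- cohort[[src]]
    if (isTRUE(spec$centering)) x <- x - mean(x)
    cols[[cv]] <- x
  }

  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  term_map <- stats::setNames(as.list(seq_len(ncol(x))), colnames(x))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("design matrix is rank deficient; offending columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = x, term_map = term_map, rank = qx$rank,
                 spec = spec,
                 factors = cohort[intersect(
                   c("del22q11", "asd", "gender", "site"), names(cohort))]),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$X), " subjects x ", ncol(x$X),
      " columns (rank ", x$rank, ")\n", sep = "")
  cat("  terms:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}
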