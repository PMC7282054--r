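#' Fit the vertex-wise GLM
#'
#' Ordinary least squares of every vertex's values on the design matrix
#' (massively univariate: one independent fit per vertex, no spatial
#' regularisation). Residuals are retained for smoothness (resel)
#' estimation.
#'
#' @param design A [build_design()] object.
#' @param metrics Subjects x vertices matrix of one metric's maps.
#' @return An object of class `vertex_glm`: `coefficients` and
#'   `standard_errors` (terms x vertices), `residuals` (subjects x
#'   vertices), `sigma` (per-vertex residual SD), `dof` (n - rank),
#'   `design` (the input design). Vertices with zero residual variance get
#'   `NaN` t statistics rather than fabricated values.
#' @export
fit_vertex_glm <- function(design, metrics) {
  x <- design$X
  stopifnot(is.matrix(metrics), nrow(metrics) == nrow(x))
  qx <- qr(x)
  coef <- qr.coef(qx, metrics)
  fitted <- x %*% coef
  res <- metrics - fitted
  dof <- nrow(x) - design$rank
  sigma <- sqrt(colSums(res^2) / dof)
  xtx_inv_diag <- diag(chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot),
                                          drop = FALSE])
  se <- sqrt(xtx_inv_diag) %o% sigma
  dimnames(coef) <- dimnames(se) <- list(colnames(x), NULL)
  structure(list(coefficients = coef, standard_errors = se,
                 residuals = res, sigma = sigma, dof = dof,
                 design = design),
            class = "vertex_glm")
}

#' @export
print.vertex_glm <- function(x, ...) {
  cat("<vertex_glm> ", ncol(x$coefficients), " vertices, ",
      nrow(x$coefficients), " terms, residual dof ", x$dof, "\n", sep = "")
  invisible(x)
}

new_statmap <- function(values, kind, term, dof) {
  structure(list(values = values, kind = kind, term = term, dof = dof),
            class = "statmap")
}

#' @export
print.statmap <- function(x, ...) {
  cat("<statmap> ", x$kind, " map for term '", x$term, "' (",
      length(x$values), " vertices, dof ", x$dof, "); range [",
      round(min(x$values, na.rm = TRUE), 2), ", ",
      round(max(x$values, na.rm = TRUE), 2), "]\n", sep = "")
  invisible(x)
}

#' Per-vertex t map for a model term
#'
#' `t = coefficient / standard error`, per vertex.
#'
#' @param fit A [fit_vertex_glm()] object.
#' @param term Term name, e.g. `"del22q11"`, `"asd"`, `"interaction"`.
#' @return A `statmap` of kind `"t"` with the fit's residual dof.
#' @export
contrast_tmap <- function(fit, term) {
  if (!term %in% rownames(fit$coefficients)) stop("unknown term: ", term)
  b <- fit$coefficients[term, ]
  se <- fit$standard_errors[term, ]
  t <- ifelse(se > 0, b / se, NaN)
  new_statmap(t, "t", term, fit$dof)
}

#' Cohen's-d-type effect-size map for a two-level factor term
#'
#' `d = t * sqrt(1/n_a + 1/n_b)` with the marginal group sizes of the
#' factor (carriers vs non-carriers for `del22q11`, ASD vs non-ASD for
#' `asd`).
#'
#' @inheritParams contrast_tmap
#' @return A `statmap` of kind `"cohen_d"`.
#' @export
effect_size_map <- function(fit, term) {
  fac <- fit$design$factors
  levels2 <- switch(term,
    del22q11 = fac$del22q11,
    asd = fac$asd,
    gender = if (!is.null(fac$gender)) as.integer(fac$gender) else NULL,
    stop("term '", term, "' is not a two-level factor contrast"))
  if (is.null(levels2)) stop("term '", term, "' is not available")
  tab <- table(levels2)
  if (length(tab) != 2) stop("term '", term, "' is not a two-level factor contrast")
  tmap <- contrast_tmap(fit, term)
  scale <- sqrt(1 / tab[[1]] + 1 / tab[[2]])
  new_statmap(tmap$values * scale, "cohen_d", term, fit$dof)
}

#' Tidy a statmap into a tibble
#'
#' @param x A `statmap`.
#' @param ... Unused.
#' @return A tibble with `vertex`, `value`, `kind`, `term`.
#' @export
tidy.statmap <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$values), value = x$values,
                 kind = x$kind, term = x$term)
}
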