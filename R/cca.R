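#' Canonical correlation analysis (backward model)
#'
#' Fits the backward model `xhat = W' x`: weight matrices `Wx`, `Wy`
#' maximising the successive correlations of the variate pairs under
#' within-side orthonormality of variate scores, computed by singular value
#' decomposition of the whitened cross-covariance
#' `Sxx^-1/2 Sxy Syy^-1/2` on standardized columns (correlation-matrix
#' CCA, so loadings are scale-free correlations). Loadings are the
#' correlations of each observed column with its own side's variate
#' scores. Each variate's sign is fixed so that the clinical variable with
#' the largest absolute loading loads positively.
#'
#' @param x Subjects x p brain-feature matrix (or `region_features`
#'   tibble); requires `p < n`.
#' @param y Subjects x q clinical matrix; requires `q < n`.
#' @param max_condition Condition-number guard on either correlation
#'   matrix.
#' @return An object of class `cca_fit`: `wx` (p x s), `wy` (q x s),
#'   `scores_x`, `scores_y` (subjects x s, unit variance, mutually
#'   uncorrelated within side), `cor` (s canonical correlations,
#'   non-increasing), `loadings_x`, `loadings_y`, `order`, `sign_flip`,
#'   `n`, `p`, `q`.
#' @export
fit_cca <- function(x, y, max_condition = 1e10) {
  if (inherits(x, "region_features")) x <- feature_matrix(x)
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  stopifnot(nrow(y) == n)
  p <- ncol(x); q <- ncol(y)
  if (p >= n || q >= n) {
    stop("classical CCA needs fewer features than samples (p = ", p,
         ", q = ", q, ", n = ", n, ")")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(q))
  sx <- apply(x, 2, stats::sd); sy <- apply(y, 2, stats::sd)
  if (any(sx == 0) || any(sy == 0)) stop("zero-variance column")
  xs <- scale(x); ys <- scale(y)
  sxx <- stats::cor(x); syy <- stats::cor(y); sxy <- crossprod(xs, ys) / (n - 1)
  for (m in list(sxx, syy)) {
    if (kappa(m, exact = FALSE) > max_condition) {
      stop("collinear columns: correlation matrix condition number above ",
           format(max_condition))
    }
  }
  cx <- chol(sxx); cy <- chol(syy)
  m <- backsolve(cx, sxy, transpose = TRUE)      # Cx^-T Sxy       (p x q)
  m <- t(backsolve(cy, t(m), transpose = TRUE))  # Cx^-T Sxy Cy^-1
  sv <- svd(m)
  s <- min(p, q)
  wx <- backsolve(cx, sv$u[, seq_len(s), drop = FALSE])
  wy <- backsolve(cy, sv$v[, seq_len(s), drop = FALSE])
  rho <- pmin(1, sv$d[seq_len(s)])
  scores_x <- xs %*% wx
  scores_y <- ys %*% wy
  loadings_x <- stats::cor(xs, scores_x)
  loadings_y <- stats::cor(ys, scores_y)

  sign_flip <- rep(1, s)
  for (i in seq_len(s)) {
    top <- which.max(abs(loadings_y[, i]))
    if (loadings_y[top, i] < 0) sign_flip[i] <- -1
  }
  wx <- sweep(wx, 2, sign_flip, "*"); wy <- sweep(wy, 2, sign_flip, "*")
  scores_x <- sweep(scores_x, 2, sign_flip, "*")
  scores_y <- sweep(scores_y, 2, sign_flip, "*")
  loadings_x <- sweep(loadings_x, 2, sign_flip, "*")
  loadings_y <- sweep(loadings_y, 2, sign_flip, "*")

  vn <- paste0("cv", seq_len(s))
  dimnames(wx) <- list(colnames(x), vn); dimnames(wy) <- list(colnames(y), vn)
  colnames(scores_x) <- colnames(scores_y) <- vn
  dimnames(loadings_x) <- list(colnames(x), vn)
  dimnames(loadings_y) <- list(colnames(y), vn)
  structure(list(wx = wx, wy = wy, scores_x = scores_x,
                 scores_y = scores_y, cor = rho,
                 loadings_x = loadings_x, loadings_y = loadings_y,
                 order = seq_len(s), sign_flip = sign_flip,
                 n = n, p = p, q = q),
            class = "cca_fit")
}

#' @export
print.cca_fit <- function(x, ...) {
  cat("<cca_fit> n = ", x$n, ", p = ", x$p, ", q = ", x$q, "\n", sep = "")
  cat("  canonical correlations:",
      paste(round(x$cor, 3), collapse = ", "), "\n")
  invisible(x)
}

#' RV coefficient with a permutation test
#'
#' Overall multivariate association between two matrices:
#' `RV = tr(Sxy Syx) / sqrt(tr(Sxx Sxx) tr(Syy Syy))` on column-centred
#' data, with a permutation p-value from row permutations of `y`
#' (`p = (1 + #{RV_perm >= RV}) / (n_permutations + 1)`).
#'
#' @param x,y Subjects x variables matrices.
#' @param n_permutations Number of row permutations (>= 1).
#' @param seed Integer seed for the permutations.
#' @return A tibble with `rv`, `p_value`, `n_permutations`.
#' @export
rv_coefficient <- function(x, y, n_permutations = 999, seed = 1) {
  if (inherits(x, "region_features")) x <- feature_matrix(x)
  stopifnot(n_permutations >= 1)
  x <- scale(as.matrix(x), scale = FALSE)
  y <- scale(as.matrix(y), scale = FALSE)
  rv_stat <- function(yy) {
    sxy <- crossprod(x, yy)
    sum(sxy^2) / sqrt(sum(crossprod(x)^2) * sum(crossprod(yy)^2))
  }
  obs <- rv_stat(y)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(i) rv_stat(y[sample(nrow(y)), , drop = FALSE]),
                 numeric(1))
  tibble::tibble(rv = obs,
                 p_value = (1 + sum(perm >= obs)) / (n_permutations + 1),
                 n_permutations = n_permutations)
}

#' Wilks' lambda from canonical correlations
#'
#' `Lambda_k = prod_{i >= k} (1 - r_i^2)`; `1 - Lambda_1` is the
#' R-square-type effect size of the full canonical model.
#'
#' @param rho Canonical correlations in `[0, 1]`.
#' @param start_index Drop the first `start_index - 1` variates.
#' @export
wilks_lambda <- function(rho, start_index = 1) {
  if (any(rho < 0 | rho > 1)) stop("canonical correlations outside [0, 1]")
  prod(1 - rho[start_index:length(rho)]^2)
}

#' Rao's F approximation for Wilks' lambda
#'
#' @param lambda Wilks' lambda of the full model.
#' @param n,p,q Sample size and the two variable-set sizes.
#' @return A tibble with `f`, `df1`, `df2`, `p_value`.
#' @export
rao_f <- function(lambda, n, p, q) {
  if (p^2 + q^2 == 5) stop("Rao's t undefined for p^2 + q^2 = 5")
  t <- sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5))
  w <- n - 1 - (p + q + 1) / 2
  df1 <- p * q
  df2 <- floor(w * t - p * q / 2 + 1)
  if (df2 <= 0) stop("non-positive df2")
  lt <- lambda^(1 / t)
  f <- ((1 - lt) / lt) * (df2 / df1)
  tibble::tibble(f = f, df1 = df1, df2 = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Pillai's trace and its F approximation
#'
#' @param rho Canonical correlations.
#' @inheritParams rao_f
#' @return A tibble with `v`, `f`, `df1`, `df2`, `p_value`.
#' @export
pillai_trace <- function(rho, n, p, q) {
  v <- sum(rho^2)
  s <- min(p, q)
  if (v >= s) stop("Pillai's trace must be below s = min(p, q)")
  m <- (abs(p - q) - 1) / 2
  nn <- (n - p - q - 2) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  f <- ((2 * nn + s + 1) / (2 * m + s + 1)) * (v / (s - v))
  tibble::tibble(v = v, f = f, df1 = df1, df2 = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Bartlett's sequential chi-squared test
#'
#' Tests variates `k, ..., s` jointly:
#' `chi2_k = -(n - 1 - (p + q + 1) / 2) * log(Lambda_k)` with
#' `df = (p - k + 1)(q - k + 1)`.
#'
#' @inheritParams pillai_trace
#' @param start_index First variate retained in the test.
#' @return A tibble with `start_index`, `chi2`, `df`, `p_value`.
#' @export
bartlett_chi2 <- function(rho, start_index, n, p, q) {
  lam <- wilks_lambda(rho, start_index)
  if (lam <= 0) stop("Wilks' lambda is zero; chi-squared undefined")
  chi2 <- -(n - 1 - (p + q + 1) / 2) * log(lam)
  df <- (p - start_index + 1) * (q - start_index + 1)
  tibble::tibble(start_index = start_index, chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Variate adequacies and redundancies
#'
#' Adequacy of variate `i` for a side is the mean squared loading of that
#' side's variables on the variate (x100, percent of the side's variance
#' the variate carries); redundancy multiplies the clinical adequacy by the
#' squared canonical correlation (percent of clinical variance explained by
#' the brain variate).
#'
#' @param fit A [fit_cca()] object.
#' @return A tibble with one row per variate: `variate`, `cor`,
#'   `adequacy_x`, `adequacy_y`, `redundancy`; total redundancy is the
#'   column sum.
#' @export
adequacy_redundancy <- function(fit) {
  if (is.null(fit$loadings_x) || is.null(fit$loadings_y)) {
    stop("fit carries no loadings")
  }
  adequacy_x <- 100 * colMeans(fit$loadings_x^2)
  adequacy_y <- 100 * colMeans(fit$loadings_y^2)
  tibble::tibble(variate = seq_along(fit$cor), cor = fit$cor,
                 adequacy_x = adequacy_x, adequacy_y = adequacy_y,
                 redundancy = adequacy_y * fit$cor^2)
}

#' Full significance and adequacy report for a CCA fit
#'
#' Bundles the RV coefficient (optional), Wilks' lambda with Rao's F,
#' Pillai's trace, Bartlett's sequential tests for every start index, and
#' per-variate adequacy/redundancy.
#'
#' @param fit A [fit_cca()] object.
#' @param x,y The matrices the fit was computed from; needed only when
#'   `n_permutations > 0` for the RV test.
#' @param n_permutations Permutations for the RV test (0 skips it).
#' @param seed Seed for the RV permutations.
#' @return A `cca_report` list: `rv` (tibble or `NULL`), `wilks`
#'   (`lambda`, `rho_sq`, Rao's F tibble), `pillai`, `bartlett` (tibble
#'   over start indices), `adequacy` (per-variate tibble),
#'   `total_redundancy`.
#' @export
cca_significance <- function(fit, x = NULL, y = NULL, n_permutations = 0,
                             seed = 1) {
  rho <- fit$cor
  lam <- wilks_lambda(rho)
  bart <- dplyr::bind_rows(lapply(seq_along(rho), function(k) {
    bartlett_chi2(rho, k, fit$n, fit$p, fit$q)
  }))
  rv <- NULL
  if (n_permutations > 0) {
    if (is.null(x) || is.null(y)) stop("RV test needs x and y")
    rv <- rv_coefficient(x, y, n_permutations, seed)
  }
  structure(list(
    rv = rv,
    wilks = list(lambda = lam, rho_sq = 1 - lam,
                 rao = rao_f(lam, fit$n, fit$p, fit$q)),
    pillai = pillai_trace(rho, fit$n, fit$p, fit$q),
    bartlett = bart,
    adequacy = adequacy_redundancy(fit),
    total_redundancy = sum(adequacy_redundancy(fit)$redundancy)
  ), class = "cca_report")
}

#' @export
print.cca_report <- function(x, ...) {
  cat("<cca_report>\n")
  cat("  Wilks' lambda = ", signif(x$wilks$lambda, 3), " (rho^2 = ",
      signif(x$wilks$rho_sq, 3), "), Rao F(", x$wilks$rao$df1, ", ",
      x$wilks$rao$df2, ") = ", round(x$wilks$rao$f, 2), "\n", sep = "")
  cat("  Pillai's trace = ", round(x$pillai$v, 2), ", F(", x$pillai$df1,
      ", ", x$pillai$df2, ") = ", round(x$pillai$f, 2), "\n", sep = "")
  if (!is.null(x$rv)) {
    cat("  RV = ", signif(x$rv$rv, 3), " (p = ", signif(x$rv$p_value, 2),
        ")\n", sep = "")
  }
  cat("  total redundancy = ", round(x$total_redundancy, 2), "%\n", sep = "")
  invisible(x)
}

#' Sort canonical variates by significance
#'
#' Reorders variates by ascending Bartlett p-value (ties broken by
#' descending clinical adequacy) and permutes all weight, score and
#' loading columns consistently; the applied permutation is recorded in
#' `order`.
#'
#' @param fit A [fit_cca()] object.
#' @param report The matching [cca_significance()] report.
#' @return A list with the reordered `fit` and `report`.
#' @export
sort_variates <- function(fit, report) {
  if (is.null(report$bartlett)) stop("report carries no Bartlett results")
  ord <- order(report$bartlett$p_value, -report$adequacy$adequacy_y)
  out <- fit
  out$wx <- fit$wx[, ord, drop = FALSE]
  out$wy <- fit$wy[, ord, drop = FALSE]
  out$scores_x <- fit$scores_x[, ord, drop = FALSE]
  out$scores_y <- fit$scores_y[, ord, drop = FALSE]
  out$cor <- fit$cor[ord]
  out$loadings_x <- fit$loadings_x[, ord, drop = FALSE]
  out$loadings_y <- fit$loadings_y[, ord, drop = FALSE]
  out$sign_flip <- fit$sign_flip[ord]
  out$order <- ord
  rep2 <- report
  rep2$bartlett <- report$bartlett[ord, ]
  rep2$adequacy <- report$adequacy[ord, ] |>
    dplyr::mutate(variate = dplyr::row_number())
  list(fit = out, report = rep2)
}

#' @rdname fit_cca
#' @param x A `cca_fit`.
#' @param ... Unused.
#' @export
tidy.cca_fit <- function(x, ...) {
  lx <- tibble::as_tibble(x$loadings_x, rownames = "variable") |>
    dplyr::mutate(side = "x")
  ly <- tibble::as_tibble(x$loadings_y, rownames = "variable") |>
    dplyr::mutate(side = "y")
  dplyr::bind_rows(lx, ly) |>
    tidyr::pivot_longer(dplyr::starts_with("cv"), names_to = "variate",
                        values_to = "loading") |>
    dplyr::relocate("side", "variable", "variate", "loading")
}

#' @rdname fit_cca
#' @export
glance.cca_fit <- function(x, ...) {
  lam <- wilks_lambda(x$cor)
  tibble::tibble(n = x$n, p = x$p, q = x$q, s = length(x$cor),
                 first_cor = x$cor[1], wilks_lambda = lam,
                 rho_sq = 1 - lam, pillai = sum(x$cor^2))
}
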