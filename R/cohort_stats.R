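#' Pearson chi-squared test of a contingency table
#'
#' Plain Pearson chi-squared on observed counts (no continuity
#' correction), as used for the cohort's site-by-group and gender-by-group
#' tables.
#'
#' @param counts r x c matrix of non-negative counts (>= 2 rows/columns).
#' @return A tibble with `chi2`, `df`, `p_value`.
#' @export
contingency_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) >= 2, ncol(counts) >= 2, all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero margin in contingency table")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(chi2 = unname(res$statistic), df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

#' One-way ANOVA of a covariate across groups
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of the same length.
#' @return A tibble with `f`, `df1`, `df2`, `p_value`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("every group needs >= 2 subjects")
  a <- stats::anova(stats::lm(values ~ groups))
  tibble::tibble(f = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
                 p_value = a$`Pr(>F)`[1])
}

#' Scheffe post hoc pairwise comparisons
#'
#' For each group pair, the Scheffe statistic
#' `F_pair = (mean difference)^2 / (MSE (1/n_i + 1/n_j))` is referred to
#' `(k - 1) F_{alpha, k-1, N-k}`; the adjusted p-value is
#' `P(F_{k-1, N-k} >= F_pair / (k - 1))`, which is conservative relative
#' to unadjusted pairwise t tests.
#'
#' @inheritParams oneway_anova
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble with one row per pair: `group1`, `group2`, `diff`,
#'   `f_pair`, `p_adjusted`, `significant`.
#' @export
scheffe_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 3) warning("fewer than 3 groups: Scheffe reduces to a plain t test")
  n <- length(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) /
    (n - k)
  pairs <- utils::combn(levels(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    d <- means[[g1]] - means[[g2]]
    fp <- d^2 / (mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
    p <- stats::pf(fp / (k - 1), k - 1, n - k, lower.tail = FALSE)
    tibble::tibble(group1 = g1, group2 = g2, diff = d, f_pair = fp,
                   p_adjusted = p, significant = p < alpha)
  })
}

#' Levene's test for homogeneity of variances
#'
#' Brown-Forsythe variant (absolute deviations from group medians).
#'
#' @inheritParams oneway_anova
#' @return A tibble with `w`, `df1`, `df2`, `p_value`.
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("every group needs >= 2 subjects")
  res <- car::leveneTest(values, groups, center = stats::median)
  tibble::tibble(w = res$`F value`[1], df1 = res$Df[1], df2 = res$Df[2],
                 p_value = res$`Pr(>F)`[1])
}

#' Reference worked-example inputs
#'
#' The printed summary quantities of the source cohort that the package's
#' test-statistic machinery can be run against without any subject-level
#' data: the five canonical correlations of the published full-sample CCA
#' (n = 131 subjects, p = 63 selected neuroanatomical features, q = 5 SRS
#' subdomains) and the site-by-group allocation counts.
#'
#' @return A list with `canonical_correlations` (length 5), `n`, `p`,
#'   `q`, and `site_by_group` (4 groups x 3 sites count matrix).
#' @export
#' @examples
#' ref <- reference_cohort_values()
#' wilks_lambda(ref$canonical_correlations)
reference_cohort_values <- function() {
  site <- rbind(
    `22q11.nonASD` = c(8, 17, 0),
    `22q11.ASD`    = c(17, 8, 0),
    ASD            = c(0, 0, 40),
    TD             = c(14, 14, 13)
  )
  colnames(site) <- c("IoPPN", "UCLA", "Frankfurt")
  list(canonical_correlations = c(0.822, 0.772, 0.764, 0.724, 0.653),
       n = 131L, p = 63L, q = 5L, site_by_group = site)
}
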