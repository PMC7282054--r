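#' Default cohort configuration
#'
#' Per-group distribution parameters for the synthetic cohort. The defaults
#' reproduce the published cohort's structure: four groups crossing the
#' 22q11.2 deletion with an ASD diagnosis (22q11.nonASD n = 25, 22q11.ASD
#' n = 25, idiopathic ASD n = 40, TD controls n = 41; 131 in total), three
#' acquisition sites with the observed site-by-group allocation, and group
#' means/SDs for age, full-scale IQ, total cortical volume (L), total
#' surface area (m^2), mean cortical thickness (mm) and SRS totals taken
#' from the cohort's demographic table. Ages are drawn from a truncated
#' normal on the configured range.
#'
#' @param group_sizes Named integer vector of cell sizes, order
#'   `22q11.nonASD`, `22q11.ASD`, `ASD`, `TD`.
#' @return A list of per-group parameter tables used by [simulate_cohort()].
#' @export
cohort_config <- function(group_sizes = c(`22q11.nonASD` = 25L,
                                          `22q11.ASD` = 25L,
                                          ASD = 40L, TD = 41L)) {
  groups <- c("22q11.nonASD", "22q11.ASD", "ASD", "TD")
  stopifnot(length(group_sizes) == 4)
  names(group_sizes) <- groups
  list(
    group_sizes = group_sizes,
    # P(site | group); sites IoPPN / UCLA / Frankfurt
    site_probs = rbind(
      `22q11.nonASD` = c(8, 17, 0) / 25,
      `22q11.ASD`    = c(17, 8, 0) / 25,
      ASD            = c(0, 0, 40) / 40,
      TD             = c(14, 14, 13) / 41
    ),
    male_prob = c(`22q11.nonASD` = 11 / 25, `22q11.ASD` = 13 / 25,
                  ASD = 32 / 40, TD = 23 / 41),
    age   = list(mean = c(14, 15, 15, 14), sd = c(6, 4, 2, 4),
                 range = c(6, 25)),
    fsiq  = list(mean = c(86, 81, 96, 104), sd = c(15, 12, 13, 11),
                 range = c(40, 160)),
    total_cv = list(mean = c(0.66, 0.68, 0.75, 0.73),
                    sd = c(0.08, 0.07, 0.07, 0.07), range = c(0.3, 1.1)),
    total_sa = list(mean = c(0.20, 0.21, 0.23, 0.22),
                    sd = c(0.02, 0.02, 0.02, 0.02), range = c(0.1, 0.32)),
    mean_ct  = list(mean = c(2.78, 2.77, 2.71, 2.71),
                    sd = c(0.13, 0.10, 0.10, 0.10), range = c(2.2, 3.3)),
    # SRS totals per group; split proportionally across the 5 subdomains
    srs_total = list(mean = c(55, 101, 95, 23), sd = c(26, 33, 29, 19),
                     range = c(0, 200)),
    # fraction of the SRS total carried by each subdomain
    srs_split = c(saw = 0.12, scg = 0.18, scm = 0.34, sm = 0.16, rrb = 0.20)
  )
}

group_levels <- function() c("22q11.nonASD", "22q11.ASD", "ASD", "TD")
srs_domains <- function() c("saw", "scg", "scm", "sm", "rrb")

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd < 0) stop("negative SD")
  if (sd == 0) return(rep(mean, n))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

#' Simulate a study cohort
#'
#' Draws a cohort table with the factorial group structure, site and gender
#' allocation, covariates and SRS subdomain scores configured in
#' [cohort_config()]. Group cell sizes are exact (not sampled); covariates
#' come from truncated normals. SRS subdomains are drawn here without any
#' brain-behaviour link; [simulate_clinical_scores()] can later replace them
#' with scores carrying a planted canonical structure.
#'
#' @param config A [cohort_config()] list.
#' @param seed Integer seed; a fixed seed yields a bit-identical cohort.
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `del22q11`, `asd` (0/1 integers), `site`, `gender`, `age`, `age2`,
#'   `fsiq`, `total_cv` (L), `total_sa` (m^2), `mean_ct` (mm), the five
#'   `srs_*` subdomain scores and `srs_total`.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' dplyr::count(cohort, group)
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  sizes <- config$group_sizes
  if (any(sizes < 1)) stop("empty group in config$group_sizes")
  for (nm in c("age", "fsiq", "total_cv", "total_sa", "mean_ct", "srs_total")) {
    if (any(config[[nm]]$sd < 0)) stop("negative SD for ", nm)
  }
  set.seed(seed)
  groups <- group_levels()
  rows <- purrr::map(seq_along(groups), function(gi) {
    g <- groups[gi]
    n <- sizes[[g]]
    draw <- function(par) {
      rtruncnorm(n, par$mean[gi], par$sd[gi], par$range[1], par$range[2])
    }
    # each subdomain drawn separately (share of the group total mean/SD);
    # the SRS total is their sum by construction
    srs <- vapply(config$srs_split, function(share) {
      pmax(0, rtruncnorm(n, share * config$srs_total$mean[gi],
                         share * config$srs_total$sd[gi],
                         0, share * config$srs_total$range[2]))
    }, numeric(n))
    srs <- matrix(srs, nrow = n,
                  dimnames = list(NULL, paste0("srs_", srs_domains())))
    tibble::tibble(
      group = g,
      del22q11 = as.integer(g %in% c("22q11.nonASD", "22q11.ASD")),
      asd = as.integer(g %in% c("22q11.ASD", "ASD")),
      site = sample(c("IoPPN", "UCLA", "Frankfurt"), n, replace = TRUE,
                    prob = config$site_probs[g, ]),
      gender = sample(c("male", "female"), n, replace = TRUE,
                      prob = c(config$male_prob[[g]], 1 - config$male_prob[[g]])),
      age = draw(config$age),
      fsiq = draw(config$fsiq),
      total_cv = draw(config$total_cv),
      total_sa = draw(config$total_sa),
      mean_ct = draw(config$mean_ct)
    ) |>
      dplyr::bind_cols(tibble::as_tibble(srs))
  })
  cohort <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      subject_id = sprintf("sub%03d", dplyr::row_number()),
      group = factor(.data$group, levels = groups),
      site = factor(.data$site, levels = c("IoPPN", "UCLA", "Frankfurt")),
      gender = factor(.data$gender, levels = c("female", "male")),
      age2 = .data$age^2,
      srs_total = .data$srs_saw + .data$srs_scg + .data$srs_scm +
        .data$srs_sm + .data$srs_rrb
    ) |>
    dplyr::relocate("subject_id", "group", "del22q11", "asd", "site",
                    "gender", "age", "age2", "fsiq")
  cohort
}

#' Tabulate the 2x2 cell sizes of a cohort
#'
#' @param cohort A [simulate_cohort()] tibble.
#' @return A tibble with `del22q11`, `asd` and `n`.
#' @export
group_cell_sizes <- function(cohort) {
  dplyr::count(cohort, .data$del22q11, .data$asd)
}
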