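#' Plot a per-vertex stat map in spherical coordinates
#'
#' Flattens the toy sphere to longitude/latitude and colours vertices by
#' the map value — a quick diagnostic view, not an anatomical rendering.
#'
#' @param statmap A `statmap` (from [contrast_tmap()] or
#'   [effect_size_map()]).
#' @param mesh The mesh the map lives on.
#' @return A ggplot object.
#' @export
plot_statmap <- function(statmap, mesh) {
  v <- mesh$vertices
  df <- tibble::tibble(
    lon = atan2(v[, 2], v[, 1]) * 180 / pi,
    lat = asin(pmin(1, pmax(-1, v[, 3] / sqrt(rowSums(v^2))))) * 180 / pi,
    value = statmap$values
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_gradient2(low = "cyan", mid = "grey85",
                                    high = "red", midpoint = 0) +
    ggplot2::labs(title = paste0(statmap$kind, " map: ", statmap$term),
                  x = "longitude", y = "latitude",
                  colour = statmap$kind) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.statmap <- function(object, mesh, ...) plot_statmap(object, mesh)

#' Plot canonical variate scores
#'
#' Scatter of a brain-side versus clinical-side variate pair, optionally
#' coloured by group.
#'
#' @param object A [fit_cca()] object.
#' @param variate Variate index.
#' @param group Optional factor to colour by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cca_fit <- function(object, variate = 1, group = NULL, ...) {
  df <- tibble::tibble(xhat = object$scores_x[, variate],
                       yhat = object$scores_y[, variate])
  if (!is.null(group)) df$group <- group
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$xhat, .data$yhat))
  p <- if (is.null(group)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.8)
  }
  p +
    ggplot2::labs(
      x = sprintf("brain variate %d", variate),
      y = sprintf("clinical variate %d", variate),
      title = sprintf("canonical variate pair %d (r = %.2f)", variate,
                      object$cor[variate])) +
    ggplot2::theme_minimal()
}

#' Plot carrier vs non-carrier loadings
#'
#' Scatter of group-specific forward-model loadings for one variate, with
#' the identity line; points far from the diagonal are candidates for
#' significant Fisher-Z loading differences.
#'
#' @param comparison A [compare_groups()] result.
#' @param variate Variate index.
#' @return A ggplot object.
#' @export
plot_loading_comparison <- function(comparison, variate = 1) {
  df <- dplyr::filter(comparison$tests, .data$variate == !!variate)
  ggplot2::ggplot(df, ggplot2::aes(.data$r_noncarrier, .data$r_carrier,
                                   colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "non-carrier loading", y = "carrier loading",
                  title = sprintf(
                    "neuroanatomical loadings, variate %d (phi = %.2f)",
                    variate, comparison$congruence$phi_x[variate])) +
    ggplot2::theme_minimal()
}
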