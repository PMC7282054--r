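#' Stepwise-AIC feature selection against the SRS subdomains
#'
#' For each clinical outcome independently, runs a greedy stepwise
#' regression from the intercept-only model: at every step all single
#' feature additions (and, for `direction = "both"` or `"backward"`,
#' single drops) are scored by `AIC = n * log(RSS / n) + 2 k` and the best
#' AIC-decreasing move is taken, until no move improves the criterion or
#' `max_features` is reached. The selected set is the union of the five
#' final models, which is how a per-outcome selection can exceed any single
#' model's size. The procedure is deterministic given its inputs.
#'
#' @param features A standardized `region_features` tibble (or plain
#'   subjects x p matrix).
#' @param clinical Subjects x q matrix or tibble of outcome scores (the
#'   five SRS subdomains in the pipeline).
#' @param direction `"both"` (default), `"forward"` or `"backward"`-capable
#'   stepping; `"backward"` still starts from the null model but may drop
#'   previously added features.
#' @param max_features Per-outcome model size cap (< n - q - 1).
#' @return A `feature_selection` list: `selected` (character feature
#'   names, union), `per_outcome` (named list of final model feature sets)
#'   and `paths` (tibble of outcome, step, move, feature, aic).
#' @export
stepwise_aic_select <- function(features, clinical,
                                direction = c("both", "forward"),
                                max_features = NULL) {
  direction <- match.arg(direction)
  x <- if (is.matrix(features)) features else feature_matrix(features)
  y <- as.matrix(clinical)
  stopifnot(nrow(x) == nrow(y))
  if (any(!is.finite(y))) stop("non-finite clinical values")
  n <- nrow(x)
  q <- ncol(y)
  if (is.null(max_features)) max_features <- n - q - 2L
  stopifnot(max_features < n - q - 1)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))

  aic_of <- function(cols, yv) {
    xm <- cbind(1, x[, cols, drop = FALSE])
    rss <- sum(stats::lm.fit(xm, yv)$residuals^2)
    n * log(rss / n) + 2 * (length(cols) + 1)
  }

  paths <- list()
  per_outcome <- list()
  for (oi in seq_len(q)) {
    yv <- y[, oi]
    current <- character(0)
    aic <- aic_of(current, yv)
    paths[[length(paths) + 1]] <- tibble::tibble(
      outcome = colnames(y)[oi], step = 0L, move = "start",
      feature = NA_character_, aic = aic)
    step <- 0L
    repeat {
      step <- step + 1L
      cand <- list()
      if (length(current) < max_features) {
        for (f in setdiff(colnames(x), current)) {
          cand[[length(cand) + 1]] <- list(move = "add", feature = f,
                                           cols = c(current, f))
        }
      }
      if (direction == "both" && length(current) > 0) {
        for (f in current) {
          cand[[length(cand) + 1]] <- list(move = "drop", feature = f,
                                           cols = setdiff(current, f))
        }
      }
      if (length(cand) == 0) break
      aics <- vapply(cand, function(cd) aic_of(cd$cols, yv), numeric(1))
      best <- which.min(aics)
      if (aics[best] >= aic - 1e-10) break
      current <- cand[[best]]$cols
      aic <- aics[best]
      paths[[length(paths) + 1]] <- tibble::tibble(
        outcome = colnames(y)[oi], step = step,
        move = cand[[best]]$move, feature = cand[[best]]$feature, aic = aic)
    }
    per_outcome[[colnames(y)[oi]]] <- current
  }
  selected <- unique(unlist(per_outcome))
  structure(list(selected = selected, per_outcome = per_outcome,
                 paths = dplyr::bind_rows(paths), criterion = "AIC",
                 direction = direction),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> ", length(x$selected),
      " features selected (union over ", length(x$per_outcome),
      " outcomes, ", x$direction, "-direction stepwise AIC)\n", sep = "")
  for (o in names(x$per_outcome)) {
    cat("  ", o, ": ", length(x$per_outcome[[o]]), " features\n", sep = "")
  }
  invisible(x)
}
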