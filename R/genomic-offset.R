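# Genetic offset: per-cell Euclidean distance between current and future
# climates after both are mapped through the fitted turnover functions.
# Computed in the full transformed (cumulative-importance) space of all
# retained predictors, not a PCA reduction. Climate-only mismatch measure:
# no migration or biotic adjustment.

#' Genetic offset between current and future climates
#'
#' @param model a [turnover_model][fit_gf].
#' @param current,future climate grids sharing `cell_id` and the model's
#'   predictors; mismatched cell sets are an error listing the symmetric
#'   difference.
#' @param predictors predictor subset (default: all in the model).
#' @param scenario label attached to the result (default: the future
#'   grid's `"scenario"` attribute, if any).
#' @return tibble of class `offset_grid`, sorted by `cell_id`: `cell_id`,
#'   `lon`/`lat` when present, `offset`, `scenario`.
#' @export
compute_offset <- function(model, current, future, predictors = NULL,
                           scenario = NULL) {
  stopifnot(inherits(model, "turnover_model"))
  if (!"cell_id" %in% names(current) || !"cell_id" %in% names(future)) {
    abort("grids need a `cell_id` column")
  }
  only_cur <- setdiff(current$cell_id, future$cell_id)
  only_fut <- setdiff(future$cell_id, current$cell_id)
  if (length(only_cur) || length(only_fut)) {
    abort(sprintf(
      "cell sets differ: %d only in current (%s...), %d only in future (%s...)",
      length(only_cur), paste(utils::head(only_cur, 3), collapse = ","),
      length(only_fut), paste(utils::head(only_fut, 3), collapse = ",")))
  }
  current <- dplyr::arrange(current, .data$cell_id)
  future <- dplyr::arrange(future, .data$cell_id)
  tc <- transform_grid(model, current, predictors)
  tf <- transform_grid(model, future, predictors)
  off <- sqrt(rowSums((tc$comp - tf$comp)^2))
  out <- tc$cells
  out$offset <- off
  out$scenario <- scenario %||% attr(future, "scenario") %||% "future"
  class(out) <- c("offset_grid", class(out))
  out
}

#' Summarize one or more offset grids
#'
#' @param grid an `offset_grid` or a (possibly named) list of them for
#'   scenario comparison.
#' @param quantiles offset quantiles to report (non-empty).
#' @param thresholds optional offsets; the count of cells exceeding each is
#'   added as a `n_above_<t>` column.
#' @return tibble with one row per scenario: `scenario`, `n_cells`, `mean`,
#'   `max`, `q<q>` columns, threshold counts.
#' @export
summarize_offset <- function(grid, quantiles = c(0, 0.25, 0.5, 0.75, 1),
                             thresholds = NULL) {
  if (length(quantiles) == 0) abort("`quantiles` must be non-empty")
  grids <- if (inherits(grid, "offset_grid")) list(grid) else grid
  purrr::map_dfr(grids, function(g) {
    if (nrow(g) == 0) abort("empty offset grid")
    qs <- quantile(g$offset, probs = quantiles, names = FALSE)
    row <- tibble(scenario = g$scenario[1], n_cells = nrow(g),
                  mean = mean(g$offset), max = max(g$offset))
    for (i in seq_along(quantiles)) {
      row[[sprintf("q%g", quantiles[i])]] <- qs[i]
    }
    for (t in thresholds) {
      row[[sprintf("n_above_%g", t)]] <- sum(g$offset > t)
    }
    row
  })
}
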