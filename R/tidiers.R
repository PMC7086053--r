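# broom-style tidiers and ggplot2 autoplot methods for the package's
# result types.

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(r = x$r, p = x$p, n_perm = x$n_perm, exact = x$exact)
}

#' @export
glance.mantel_result <- function(x, ...) tidy(x)

#' @export
tidy.rda_result <- function(x, ...) {
  tibble(term = paste0("RDA", seq_along(x$eigenvalues)),
         eigenvalue = x$eigenvalues)
}

#' @export
glance.rda_result <- function(x, ...) {
  tibble(r2 = x$r2, adj_r2 = x$adj_r2, pseudo_f = x$pseudo_f, p = x$p,
         n = x$df[["n"]], n_predictors = x$df[["p"]],
         n_conditioning = x$df[["q"]], n_perm = x$n_perm)
}

#' @export
tidy.turnover_model <- function(x, ...) x$importance

#' @export
glance.turnover_model <- function(x, ...) {
  tibble(n_predictors = length(x$predictors),
         n_snps = nrow(x$snp_stats),
         n_predictive_snps = x$n_pos_snps,
         mean_r2 = mean(pmax(x$snp_stats$r2, 0), na.rm = TRUE),
         top_predictor = x$importance$predictor[1],
         top_importance = x$importance$importance[1])
}

#' @export
tidy.fst_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(pop1 = rownames(m)[idx[, 1]], pop2 = colnames(m)[idx[, 2]],
         fst = m[idx])
}

#' @export
tidy.mem_basis <- function(x, ...) x$moran

#' @export
tidy.ordination <- function(x, ...) x$scores

#' @export
glance.ordination <- function(x, ...) {
  tibble(type = x$type, n_axes = length(x$eigenvalues),
         var_explained_1 = x$var_explained[1])
}

# turnover curves in long form (predictor, value, cumulative importance)
turnover_curves <- function(model) {
  purrr::map_dfr(model$predictors, function(v) {
    cv <- model$curves[[v]]
    tibble(predictor = v, value = cv$breaks, cumulative = cv$cum)
  })
}

#' @export
autoplot.turnover_model <- function(object, ...) {
  ggplot2::ggplot(turnover_curves(object),
                  ggplot2::aes(x = .data$value, y = .data$cumulative)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = "predictor value", y = "cumulative importance",
                  title = "Turnover functions")
}

#' @export
autoplot.offset_grid <- function(object, ...) {
  if (!all(c("lon", "lat") %in% names(object))) {
    abort("offset grid lacks lon/lat columns")
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       fill = .data$offset)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b") +
    ggplot2::labs(title = paste("Genetic offset:", object$scenario[1]))
}

#' @export
autoplot.ordination <- function(object, ...) {
  ax <- if (object$type == "dapc") c("LD1", "LD2") else c("PC1", "PC2")
  ax <- intersect(ax, names(object$scores))
  if (length(ax) < 2) abort("need at least two axes to plot")
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                               colour = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::labs(title = toupper(object$type))
}

#' Plot an RGB genomic-composition map
#'
#' @param rgb_table output of [pca_rgb()] with `lon`/`lat` columns.
#' @return a ggplot object.
#' @export
plot_rgb_map <- function(rgb_table) {
  if (!all(c("lon", "lat") %in% names(rgb_table))) abort("needs lon/lat columns")
  cols <- grDevices::rgb(rgb_table$red, rgb_table$green, rgb_table$blue,
                         maxColorValue = 255)
  ggplot2::ggplot(rgb_table, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_tile(fill = cols) +
    ggplot2::labs(title = "Genomic composition (PCA → RGB)")
}
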