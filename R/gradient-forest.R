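# Gradient-forest turnover modeling: per-SNP random-forest regressions of
# population allele frequencies on environmental predictors, aggregated into
# R2-weighted cumulative-importance ("turnover") functions along each
# predictor, plus predictor ranking/pruning and the PCA->RGB genomic
# composition map.

#' Gradient-forest configuration
#'
#' @param trees regression trees per SNP.
#' @param min_poly_pops SNPs polymorphic in fewer populations are dropped
#'   before fitting (0 disables; apply upstream if already done).
#' @param bins number of equal-width evaluation bins along each predictor.
#' @param seed integer seed fixing every forest.
#' @param positive_only aggregate only SNPs with positive out-of-bag R2?
#' @param mtry predictors tried per split (default `max(floor(p/3), 1)`).
#' @param min_node nodes at or below this size are not split.
#' @return object of class `gf_config`.
#' @export
gf_config <- function(trees = 2000, min_poly_pops = 5, bins = 201, seed = 1,
                      positive_only = TRUE, mtry = NULL, min_node = 5) {
  if (trees < 1) abort("`trees` must be >= 1")
  if (bins < 2) abort("`bins` must be >= 2")
  structure(list(trees = as.integer(trees),
                 min_poly_pops = as.integer(min_poly_pops),
                 bins = as.integer(bins), seed = as.integer(seed),
                 positive_only = isTRUE(positive_only),
                 mtry = mtry, min_node = as.integer(min_node)),
            class = "gf_config")
}

#' Fit a gradient-forest turnover model
#'
#' For each SNP a random forest regresses its population allele frequencies
#' on the predictors, recording out-of-bag R2, out-of-bag permutation
#' importance per predictor, and every split (predictor, threshold,
#' impurity improvement). Split improvements are binned along each
#' predictor, normalized by the density of observed predictor values
#' (additively smoothed histogram), scaled per SNP by its R2-weighted
#' importance share, summed over positive-R2 SNPs, and cumulated into a
#' monotone turnover function `F_p` whose maximum equals the predictor's
#' overall importance `I_p` (the mean over positive-R2 SNPs of the
#' R2-weighted per-predictor importance).
#'
#' @param freqs an [allele_freq][new_allele_freq] object (populations x SNPs response).
#' @param env environment table (`population` column plus predictors), rows
#'   covering the populations of `freqs`.
#' @param vars predictor subset (default: all numeric env columns).
#' @param config a [gf_config()].
#' @return object of class `turnover_model`: `importance` tibble
#'   (`predictor`, `importance`, rank order), `curves` (per predictor:
#'   `breaks` of length bins+1 and non-decreasing `cum` starting at 0),
#'   `snp_stats` tibble (`snp_id`, `r2`), `ranges`, `n_pos_snps`, `config`.
#' @export
fit_gf <- function(freqs, env, vars = NULL, config = gf_config()) {
  stopifnot(inherits(freqs, "allele_freq"), inherits(config, "gf_config"))
  p <- freqs$freq
  if (nrow(p) < 5) abort("need at least 5 populations")
  envx <- env[, setdiff(names(env), c("population", "cell_id")), drop = FALSE]
  envx <- envx[vapply(envx, is.numeric, logical(1))]
  if (!is.null(vars)) {
    missing_v <- setdiff(vars, names(envx))
    if (length(missing_v)) abort(sprintf("predictor(s) not in env table: %s",
                                         paste(missing_v, collapse = ", ")))
    envx <- envx[, vars, drop = FALSE]
  }
  if (ncol(envx) < 1) abort("need at least 1 predictor")
  if ("population" %in% names(env)) {
    envx <- envx[match(rownames(p), env$population), , drop = FALSE]
  }
  if (anyNA(envx)) abort("missing values in predictors")
  X <- as.matrix(envx)
  predictors <- colnames(X)

  if (config$min_poly_pops > 0) {
    poly <- colSums(p > 0 & p < 1, na.rm = TRUE)
    keep <- poly >= config$min_poly_pops
    p <- p[, keep, drop = FALSE]
    freqs_snps <- freqs$snps[keep, , drop = FALSE]
  } else {
    freqs_snps <- freqs$snps
  }
  if (ncol(p) == 0) abort("no SNPs left after the polymorphism filter")
  if (anyNA(p)) {
    # frequencies undefined where a population had no genotyped alleles
    mu <- colMeans(p, na.rm = TRUE)
    for (j in which(colSums(is.na(p)) > 0)) p[is.na(p[, j]), j] <- mu[j]
    warn("mean-imputed undefined allele-frequency cells before fitting")
  }

  mtry <- config$mtry %||% max(floor(ncol(X) / 3), 1L)
  set.seed(config$seed)
  fits <- lapply(seq_len(ncol(p)), function(j) {
    gf_forest_cpp(X, p[, j], config$trees, as.integer(mtry), config$min_node)
  })
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  imp_raw <- t(vapply(fits, `[[`, numeric(ncol(X)), "importance"))
  imp_raw[imp_raw < 0] <- 0
  colnames(imp_raw) <- predictors

  pos <- which(!is.na(r2) & r2 > 0)
  if (config$positive_only && length(pos) == 0) abort("no predictive SNPs")
  use <- if (config$positive_only) pos else seq_along(fits)
  n_pos <- length(use)

  # zero out importances with no recorded splits, then R2-weighted shares
  has_splits <- matrix(FALSE, length(fits), ncol(X))
  for (s in seq_along(fits)) {
    sv <- fits[[s]]$splits[, "var"]
    if (length(sv)) has_splits[s, unique(sv)] <- TRUE
  }
  imp_eff <- imp_raw * has_splits
  weighted <- matrix(0, length(fits), ncol(X), dimnames = list(NULL, predictors))
  for (s in use) {
    tot <- sum(imp_eff[s, ])
    if (tot > 0) weighted[s, ] <- r2[s] * imp_eff[s, ] / tot
  }
  importance_overall <- colSums(weighted[use, , drop = FALSE]) / n_pos

  ranges <- apply(X, 2, range)
  curves <- list()
  for (v in seq_along(predictors)) {
    lo <- ranges[1, v]; hi <- ranges[2, v]
    if (hi <= lo) hi <- lo + 1e-9
    breaks <- seq(lo, hi, length.out = config$bins + 1L)
    obs_cnt <- tabulate(findInterval(X[, v], breaks, rightmost.closed = TRUE,
                                     all.inside = TRUE), config$bins)
    total <- rep(0, config$bins)
    for (s in use) {
      if (weighted[s, v] <= 0) next
      sp <- fits[[s]]$splits
      rows <- sp[, "var"] == v
      if (!any(rows)) next
      b <- findInterval(sp[rows, "threshold"], breaks,
                        rightmost.closed = TRUE, all.inside = TRUE)
      raw <- tapply(sp[rows, "improvement"], factor(b, levels = seq_len(config$bins)),
                    sum, default = 0)
      u <- as.numeric(raw) / (obs_cnt + 1)          # density normalization
      if (sum(u) > 0) total <- total + weighted[s, v] * u / sum(u)
    }
    curves[[predictors[v]]] <- list(breaks = breaks,
                                    cum = c(0, cumsum(total)) / n_pos)
  }

  structure(list(
    predictors = predictors,
    importance = tibble(predictor = predictors,
                        importance = importance_overall) |>
      dplyr::arrange(dplyr::desc(.data$importance)),
    curves = curves,
    snp_stats = tibble(snp_id = freqs_snps$snp_id, r2 = r2),
    ranges = ranges,
    n_pos_snps = n_pos,
    config = config
  ), class = "turnover_model")
}

#' @export
print.turnover_model <- function(x, ...) {
  cat(sprintf("<turnover_model> %d predictors, %d SNPs aggregated (top: %s, I = %.4g)\n",
              length(x$predictors), x$n_pos_snps,
              x$importance$predictor[1], x$importance$importance[1]))
  invisible(x)
}

#' Construct a turnover model from explicit piecewise-linear curves
#'
#' Builds a `turnover_model` directly from cumulative-importance curves,
#' bypassing forest fitting; handy for analysing offset geometry with known
#' turnover functions.
#'
#' @param curves named list; each element a list with numeric `breaks`
#'   (increasing) and `cum` (non-decreasing, same length, starting at 0).
#' @return object of class `turnover_model`.
#' @export
piecewise_turnover_model <- function(curves) {
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    if (length(cv$breaks) != length(cv$cum)) abort("breaks/cum length mismatch")
    if (is.unsorted(cv$breaks, strictly = TRUE)) abort("breaks must increase")
    if (is.unsorted(cv$cum)) abort("cum must be non-decreasing")
  }
  imp <- vapply(curves, function(cv) max(cv$cum), numeric(1))
  structure(list(
    predictors = names(curves),
    importance = tibble(predictor = names(curves), importance = unname(imp)) |>
      dplyr::arrange(dplyr::desc(.data$importance)),
    curves = curves,
    snp_stats = tibble(snp_id = character(), r2 = numeric()),
    ranges = vapply(curves, function(cv) range(cv$breaks), numeric(2)),
    n_pos_snps = NA_integer_,
    config = NULL
  ), class = "turnover_model")
}

#' Prune correlated predictors by ranked importance
#'
#' Greedy rule: walk predictors in descending overall importance and keep a
#' predictor only if its absolute Pearson correlation with every
#' already-kept predictor is at most `r_max`.
#'
#' @param model a fitted [turnover_model][fit_gf].
#' @param env environment table with the model's predictors.
#' @param r_max correlation ceiling.
#' @return character vector of kept predictors, in importance order.
#' @export
select_predictors <- function(model, env, r_max = 0.8) {
  stopifnot(inherits(model, "turnover_model"))
  ord <- model$importance$predictor
  x <- env[, ord, drop = FALSE]
  cm <- abs(cor(as.matrix(x)))
  kept <- character()
  for (v in ord) {
    if (all(cm[v, kept] <= r_max)) kept <- c(kept, v)
  }
  kept
}

eval_turnover <- function(curve, x) {
  # piecewise-linear interpolation, clamped to [0, max] outside the range
  approx(curve$breaks, curve$cum, xout = x, rule = 2)$y
}

#' Transform a climate grid into genomic-composition space
#'
#' Each cell's predictor values are mapped through the fitted cumulative
#' importance functions, with flat extrapolation (clamping to 0 below the
#' fitted range, to the overall importance above it).
#'
#' @param model a [turnover_model][fit_gf].
#' @param grid climate grid tibble (`cell_id`, optional `lon`/`lat`,
#'   predictor columns).
#' @param predictors predictors to transform (default: all in the model).
#' @return object of class `genomic_composition`: `cells` tibble and
#'   `comp` matrix (cells x predictors).
#' @export
transform_grid <- function(model, grid, predictors = NULL) {
  stopifnot(inherits(model, "turnover_model"))
  predictors <- predictors %||% model$predictors
  missing_p <- setdiff(predictors, names(grid))
  if (length(missing_p)) abort(sprintf("grid lacks predictor column(s): %s",
                                       paste(missing_p, collapse = ", ")))
  comp <- vapply(predictors, function(v) {
    eval_turnover(model$curves[[v]], grid[[v]])
  }, numeric(nrow(grid)))
  comp <- matrix(comp, nrow = nrow(grid),
                 dimnames = list(NULL, predictors))
  cells <- grid[, intersect(c("cell_id", "lon", "lat"), names(grid)), drop = FALSE]
  structure(list(cells = as_tibble(cells), comp = comp,
                 predictors = predictors),
            class = "genomic_composition")
}

#' Summarize a genomic composition as an RGB map
#'
#' Centered PCA of the composition matrix; the first three PC scores are
#' min-max scaled to `[0, 255]` (rounded) and assigned to the red, green
#' and blue channels. Axis signs are fixed by making the largest-|loading|
#' predictor positive. If the composition has rank below 3 the remaining
#' channels are set to 128 with a warning.
#'
#' @param comp a [genomic_composition][transform_grid].
#' @return tibble: cell columns, `PC1`-`PC3`, `red`, `green`, `blue`.
#' @export
pca_rgb <- function(comp) {
  stopifnot(inherits(comp, "genomic_composition"))
  if (nrow(comp$comp) < 3) abort("need at least 3 cells")
  pc <- prcomp(comp$comp, center = TRUE, scale. = FALSE)
  k_avail <- sum(pc$sdev > 1e-10)
  out <- comp$cells
  channels <- c("red", "green", "blue")
  if (k_avail < 3) warn(sprintf("composition rank %d < 3: filling channel(s) with 128", k_avail))
  for (k in 1:3) {
    if (k <= k_avail) {
      rot <- pc$rotation[, k]
      sgn <- if (rot[which.max(abs(rot))] < 0) -1 else 1
      s <- sgn * pc$x[, k]
      rng <- range(s)
      ch <- if (diff(rng) > 0) round(255 * (s - rng[1]) / diff(rng)) else rep(128, length(s))
    } else {
      s <- rep(0, nrow(comp$comp))
      ch <- rep(128L, nrow(comp$comp))
    }
    out[[paste0("PC", k)]] <- s
    out[[channels[k]]] <- as.integer(ch)
  }
  out
}
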