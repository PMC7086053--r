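# Ordination-based structure summaries: genotype PCA and discriminant
# analysis of principal components (DAPC) with supplied or k-means labels.
# Missing genotypes are mean-imputed per SNP before ordination; zero-variance
# SNPs are excluded with a warning.

impute_scale_geno <- function(g, scale. = TRUE) {
  x <- g$geno
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  v <- apply(x, 2, var)
  drop <- v == 0 | is.na(v)
  if (any(drop)) {
    warn(sprintf("excluding %d zero-variance SNP(s) from ordination", sum(drop)))
    x <- x[, !drop, drop = FALSE]
  }
  scale(x, center = TRUE, scale = scale.)
}

# make the largest-|loading| entry of each axis positive (deterministic sign)
fix_signs <- function(rotation, scores) {
  for (k in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, k]))
    if (rotation[i, k] < 0) {
      rotation[, k] <- -rotation[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(rotation = rotation, scores = scores)
}

#' Principal component analysis of a genotype matrix
#'
#' Genotypes are mean-imputed per SNP, centered and scaled to unit variance,
#' then decomposed. Axis signs are fixed by making the largest-|loading| SNP
#' positive on each axis.
#'
#' @param g a [genotype_matrix][new_genotype_matrix].
#' @param n_axes number of axes to retain (default: all).
#' @return object of class `ordination`: list with `scores` tibble
#'   (`sample_id`, `population`, `PC1`, ...), `eigenvalues`,
#'   `var_explained`, `loadings`, `type = "pca"`.
#' @export
genotype_pca <- function(g, n_axes = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$geno) < 2) abort("need at least 2 individuals")
  x <- impute_scale_geno(g)
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(n_axes %||% ncol(pc$x), ncol(pc$x))
  fs <- fix_signs(pc$rotation[, seq_len(k), drop = FALSE],
                  pc$x[, seq_len(k), drop = FALSE])
  eig <- pc$sdev^2
  scores <- as_tibble(fs$scores)
  names(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = dplyr::bind_cols(g$samples, scores),
    eigenvalues = eig[seq_len(k)],
    var_explained = (eig / sum(eig))[seq_len(k)],
    loadings = fs$rotation,
    type = "pca"
  ), class = "ordination")
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Linear discriminant axes are computed on retained genotype PC scores;
#' each individual's posterior assignment is the softmax of negative squared
#' distances to the cluster centroids in discriminant space. Cluster labels
#' are supplied directly (e.g. from an external model-based clustering) or
#' derived by k-means on the PC scores under a fixed seed.
#'
#' @param g a [genotype_matrix][new_genotype_matrix].
#' @param labels cluster label per individual (in `g$samples` order); if
#'   `NULL`, k-means with `k` clusters on the retained PC scores.
#' @param k number of k-means clusters when `labels` is `NULL`.
#' @param n_pcs PCs retained (default: smallest number explaining 90% of
#'   variance).
#' @param n_da discriminant axes retained (default: clusters - 1).
#' @param seed seed for k-means.
#' @return object of class `ordination` with `type = "dapc"`: discriminant
#'   `scores`, `eigenvalues` (discriminant), `posterior` matrix (rows sum
#'   to 1), `assignment`, `labels`, `n_pcs`.
#' @export
dapc <- function(g, labels = NULL, k = NULL, n_pcs = NULL, n_da = NULL,
                 seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  pca <- genotype_pca(g)
  if (is.null(n_pcs)) {
    n_pcs <- which(cumsum(pca$var_explained) >= 0.9)[1]
    if (is.na(n_pcs)) n_pcs <- length(pca$var_explained)
  }
  n_pcs <- min(n_pcs, nrow(g$geno) - 1L)
  sc <- as.matrix(pca$scores[, paste0("PC", seq_len(n_pcs)), drop = FALSE])
  if (is.null(labels)) {
    if (is.null(k)) abort("supply `labels` or `k`")
    set.seed(seed)
    labels <- paste0("cluster", kmeans(sc, centers = k, nstart = 10)$cluster)
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(sc)) abort("one label per individual required")
  tab <- table(labels)
  if (length(tab) < 2) abort("need at least 2 clusters")
  if (any(tab < 2)) {
    abort(sprintf("cluster(s) with a single member: %s",
                  paste(names(tab)[tab < 2], collapse = ", ")))
  }
  if (n_pcs >= nrow(sc)) abort("`n_pcs` must be smaller than the number of individuals")
  ld <- MASS::lda(sc, grouping = factor(labels))
  da <- sc %*% ld$scaling
  n_da <- min(n_da %||% ncol(da), ncol(da))
  da <- da[, seq_len(n_da), drop = FALSE]
  centroids <- apply(da, 2, function(col) tapply(col, labels, mean))
  centroids <- matrix(centroids, nrow = length(tab),
                      dimnames = list(names(tab), colnames(da)))
  d2 <- outer(rowSums(da^2), rep(1, nrow(centroids))) -
    2 * da %*% t(centroids) +
    outer(rep(1, nrow(da)), rowSums(centroids^2))
  logw <- -d2
  post <- exp(logw - apply(logw, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- rownames(centroids)
  scores <- as_tibble(da, .name_repair = ~paste0("LD", seq_len(n_da)))
  structure(list(
    scores = dplyr::bind_cols(g$samples, scores, tibble(cluster = labels)),
    eigenvalues = ld$svd[seq_len(n_da)]^2,
    var_explained = (ld$svd^2 / sum(ld$svd^2))[seq_len(n_da)],
    posterior = post,
    assignment = colnames(post)[max.col(post, ties.method = "first")],
    labels = labels,
    n_pcs = n_pcs,
    type = "dapc"
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination:%s> %d individuals, %d axes (%.1f%% variance on axis 1)\n",
              x$type, nrow(x$scores), length(x$eigenvalues),
              100 * x$var_explained[1]))
  invisible(x)
}
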