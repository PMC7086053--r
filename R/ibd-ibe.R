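# Geographic and environmental distance matrices and the Mantel test used
# to dissect isolation by distance from isolation by environment.

#' Construct a labelled symmetric distance matrix
#'
#' @param m symmetric non-negative matrix with zero diagonal.
#' @param metric tag: `"geographic"`, `"environmental"`,
#'   `"genetic-linearized"`, ...
#' @return matrix of class `dist_matrix` with a `metric` attribute.
#' @export
new_dist_matrix <- function(m, metric = "unknown") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("distance matrix must be square")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-12) abort("distance matrix must be symmetric")
  structure(m, metric = metric, class = c("dist_matrix", class(m)))
}

#' Pairwise geographic distances between populations
#'
#' Default metric is the great-circle (haversine) distance in km on a sphere
#' of radius 6371.0088 km. `metric = "euclidean-degrees"` gives planar
#' Euclidean distance on the raw decimal-degree coordinates, which matches
#' the common "Euclidean geographic distance" phrasing of IBD analyses.
#'
#' @param coords tibble with columns `population` (or first column as
#'   labels), `lon`, `lat` in decimal degrees.
#' @param metric `"haversine"` (km) or `"euclidean-degrees"` (degrees).
#' @return a `dist_matrix`.
#' @export
geographic_distances <- function(coords, metric = c("haversine", "euclidean-degrees")) {
  metric <- match.arg(metric)
  if (any(abs(coords$lat) > 90)) abort("latitude outside [-90, 90]")
  if (any(abs(coords$lon) > 360)) abort("longitude outside [-360, 360]")
  labels <- if ("population" %in% names(coords)) coords$population else coords[[1]]
  xy <- cbind(coords$lon, coords$lat)
  m <- if (metric == "haversine") {
    geosphere::distm(xy, fun = function(p1, p2) {
      geosphere::distHaversine(p1, p2, r = 6371008.8)
    }) / 1000
  } else {
    as.matrix(dist(xy))
  }
  dimnames(m) <- list(labels, labels)
  new_dist_matrix(m, metric = paste0("geographic-", metric))
}

#' Pairwise environmental distances between sites
#'
#' Each variable is standardized to mean 0, sd 1 across sites (so magnitudes
#' are comparable), then pairwise Euclidean distances are taken on the
#' standardized vectors.
#'
#' @param env tibble with a `population` label column plus numeric variable
#'   columns.
#' @param vars variable subset to use (default: all numeric columns).
#' @return a `dist_matrix`.
#' @export
environmental_distances <- function(env, vars = NULL) {
  labels <- if ("population" %in% names(env)) env$population else env[[1]]
  x <- env[, setdiff(names(env), c("population", "cell_id")), drop = FALSE]
  x <- x[vapply(x, is.numeric, logical(1))]
  if (!is.null(vars)) {
    missing_v <- setdiff(vars, names(x))
    if (length(missing_v)) abort(sprintf("variables not in env table: %s",
                                         paste(missing_v, collapse = ", ")))
    x <- x[, vars, drop = FALSE]
  }
  if (ncol(x) == 0) abort("no environmental variables to use")
  if (anyNA(x)) abort("missing values in environmental variables")
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0)) {
    abort(sprintf("zero-variance variable(s): %s",
                  paste(names(x)[sds == 0], collapse = ", ")))
  }
  z <- scale(as.matrix(x))
  m <- as.matrix(dist(z))
  dimnames(m) <- list(labels, labels)
  new_dist_matrix(m, metric = "environmental")
}

#' Mantel test between two distance matrices
#'
#' Correlation `r` is the Pearson correlation of the upper-triangle entries.
#' The null distribution permutes the row/column order of the second matrix
#' simultaneously; the one-sided (positive association) p-value is
#' `(#{r_perm >= r_obs} + 1) / (n_perm + 1)`. With `exact = TRUE` all `n!`
#' relabelings are enumerated and `p = #{r_perm >= r_obs} / n!` (the
#' identity permutation included), feasible for small n.
#'
#' @param d1,d2 `dist_matrix` objects (or plain symmetric matrices) with
#'   identical labels in identical order.
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate the full permutation null instead of sampling.
#' @return object of class `mantel_result` with elements `r`, `p`,
#'   `n_perm`, `seed`, `exact`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL, exact = FALSE) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) abort("matrices must have matching dimensions")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    abort("matrices must share labels in the same order")
  }
  n <- nrow(m1)
  if (n < 4) abort("need at least 4 entities")
  v1 <- upper_tri_vec(m1)
  if (sd(v1) == 0 || sd(upper_tri_vec(m2)) == 0) {
    abort("constant distance matrix: Mantel r undefined")
  }
  r_obs <- cor(v1, upper_tri_vec(m2))
  if (exact) {
    perms <- all_permutations(n)
    r_perm <- vapply(perms, function(p) cor(v1, upper_tri_vec(m2[p, p])),
                     numeric(1))
    p <- sum(r_perm >= r_obs - 1e-12) / length(perms)
    n_perm <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(v1, upper_tri_vec(m2[p, p]))
    }, numeric(1))
    p <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm, seed = seed, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, one-sided p = %.4g (%s%d permutations)\n",
              x$r, x$p, if (x$exact) "exhaustive " else "", x$n_perm))
  invisible(x)
}
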