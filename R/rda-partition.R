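# Redundancy-analysis machinery: Moran eigenvector maps (PCNM-style
# truncation at the longest minimum-spanning-tree edge), VIF screening,
# permutation-based forward selection, RDA / partial RDA with Ezekiel
# adjusted R2, and the env/geo variance-partition ledger.

# Prim's minimum spanning tree; returns the edge lengths
mst_edges <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  edges <- numeric(0)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    edges <- c(edges, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  edges
}

moran_i <- function(v, w) {
  n <- length(v)
  vc <- v - mean(v)
  (n / sum(w)) * drop(vc %*% w %*% vc) / sum(vc^2)
}

#' Moran eigenvector maps of a site layout
#'
#' Builds the PCNM-style spatial weighting matrix: pairwise distances are
#' truncated at the longest minimum-spanning-tree edge `t`; weights are
#' `1 - (d / (4 t))^2` for `d <= t` and 0 beyond; the weight matrix is
#' doubly centered and eigendecomposed. Eigenvectors with positive
#' eigenvalues are returned (orthonormal, ordered by eigenvalue), each with
#' its Moran's I and a permutation p-value for positive spatial
#' autocorrelation.
#'
#' @param coords site coordinates (`population`/label column optional,
#'   `lon`, `lat`); distances are planar Euclidean on the raw coordinates.
#' @param n_perm permutations for the Moran's I test.
#' @param seed permutation seed.
#' @return object of class `mem_basis`: `vectors` (sites x functions,
#'   orthonormal), `values`, `moran` tibble (`mem`, `eigenvalue`,
#'   `moran_i`, `expected_i`, `p`), `threshold`.
#' @export
mem_basis <- function(coords, n_perm = 999, seed = 1) {
  xy <- cbind(coords$lon, coords$lat)
  n <- nrow(xy)
  if (n < 4) abort("need at least 4 sites")
  d <- as.matrix(dist(xy))
  if (any(d[upper.tri(d)] == 0)) {
    abort("coincident sites detected: jitter the coordinates before building MEMs")
  }
  t_trunc <- max(mst_edges(d))
  w <- ifelse(d <= t_trunc, 1 - (d / (4 * t_trunc))^2, 0)
  b <- scale(t(scale(t(w), scale = FALSE)), scale = FALSE)   # double centering
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(eg$values > 1e-8 * max(abs(eg$values)))
  vectors <- eg$vectors[, pos, drop = FALSE]
  colnames(vectors) <- paste0("MEM", seq_along(pos))
  w_off <- w
  diag(w_off) <- 0
  set.seed(seed)
  moran <- purrr::map_dfr(seq_along(pos), function(k) {
    v <- vectors[, k]
    i_obs <- moran_i(v, w_off)
    i_perm <- vapply(seq_len(n_perm),
                     function(b) moran_i(v[sample.int(n)], w_off), numeric(1))
    tibble(mem = colnames(vectors)[k], eigenvalue = eg$values[pos[k]],
           moran_i = i_obs, expected_i = -1 / (n - 1),
           p = (sum(i_perm >= i_obs) + 1) / (n_perm + 1))
  })
  structure(list(vectors = vectors, values = eg$values[pos], moran = moran,
                 threshold = t_trunc, coords = as_tibble(coords)),
            class = "mem_basis")
}

#' Retain significant positive-autocorrelation eigenfunctions
#'
#' Keeps (up to) the top `n_keep` eigenfunctions whose Moran's I exceeds its
#' expectation `-1/(n-1)` with permutation p <= `alpha`.
#'
#' @param basis a [mem_basis].
#' @param n_keep maximum number of functions.
#' @param alpha significance level for Moran's I.
#' @return sites x kept matrix of eigenfunctions.
#' @export
mem_keep <- function(basis, n_keep = 3, alpha = 0.05) {
  stopifnot(inherits(basis, "mem_basis"))
  ok <- basis$moran$p <= alpha & basis$moran$moran_i > basis$moran$expected_i
  keep <- utils::head(which(ok), n_keep)
  if (!length(keep)) abort("no significant positive spatial eigenfunctions")
  basis$vectors[, keep, drop = FALSE]
}

#' Variance-inflation-factor screen
#'
#' Iteratively drops the column with the highest VIF (`1 / (1 - R2)` from
#' regressing it on the remaining columns) until all VIFs are at most
#' `vif_max`. Ties (including perfectly collinear pairs, VIF infinite) are
#' broken by dropping the later-listed column first.
#'
#' @param x numeric design matrix or data frame.
#' @param vif_max VIF ceiling.
#' @return list: `kept` (column names), `dropped` (in drop order), `vif`
#'   tibble of final VIFs.
#' @export
vif_screen <- function(x, vif_max = 10) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) < 2) abort("need at least 2 columns")
  vif_of <- function(m) {
    vapply(seq_len(ncol(m)), function(j) {
      fit <- lm.fit(cbind(1, m[, -j, drop = FALSE]), m[, j])
      r2 <- 1 - sum(fit$residuals^2) / sum((m[, j] - mean(m[, j]))^2)
      r2 <- min(r2, 1 - 1e-14)
      1 / (1 - r2)
    }, numeric(1))
  }
  dropped <- character()
  while (ncol(x) > 1) {
    v <- vif_of(x)
    if (max(v) <= vif_max) break
    worst <- max(which(v == max(v)))   # later-listed dropped first on ties
    dropped <- c(dropped, colnames(x)[worst])
    x <- x[, -worst, drop = FALSE]
  }
  v <- if (ncol(x) > 1) vif_of(x) else 1
  list(kept = colnames(x), dropped = dropped,
       vif = tibble(variable = colnames(x), vif = v))
}

# core least-squares machinery shared by rda()/forward_select()
rda_r2 <- function(y, x) {
  qx <- qr(cbind(1, x))
  fitted <- qr.fitted(qx, y)
  sum(scale(fitted, scale = FALSE)^2) / sum(scale(y, scale = FALSE)^2)
}

ezekiel <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Redundancy analysis with permutation test
#'
#' Fits a multivariate least-squares regression of the (column-centered)
#' response on the predictors, optionally after residualizing both response
#' and predictors on a conditioning set (partial RDA). `R2` is the fraction
#' of total response variance captured by the constrained fit; the simple
#' RDA's adjusted R2 is Ezekiel's `1 - (1 - R2)(n - 1)/(n - p - 1)`, and a
#' partial RDA's is the difference of Ezekiel-adjusted R2 between the full
#' (predictors + condition) and conditioning-only models. Significance uses
#' the pseudo-F `(R2/p) / ((1 - R2 - R2_cond)/(n - p - q - 1))` with row
#' permutation of the response (simple RDA) or of the reduced-model
#' residuals (partial RDA).
#'
#' @param y response matrix (e.g. populations x SNP minor-allele
#'   frequencies); centered internally per column.
#' @param x predictor matrix/data frame.
#' @param condition optional conditioning matrix/data frame.
#' @param n_perm number of permutations.
#' @param seed permutation seed.
#' @return object of class `rda_result`: `r2`, `adj_r2`, `eigenvalues` (of
#'   the fitted-value covariance), `pseudo_f`, `p`, `n_perm`, `df`.
#' @export
rda <- function(y, x, condition = NULL, n_perm = 999, seed = 1) {
  y <- scale(as.matrix(y), scale = FALSE)
  x <- scale(as.matrix(x), scale = FALSE)
  n <- nrow(y)
  p <- qr(x)$rank
  z <- NULL
  q <- 0
  if (!is.null(condition)) {
    z <- scale(as.matrix(condition), scale = FALSE)
    q <- qr(z)$rank
  }
  if (n <= p + q + 1) abort("insufficient degrees of freedom")
  ss_tot <- sum(y^2)

  stat <- function(yy) {
    if (is.null(z)) {
      qx <- qr(x)
      fit <- qr.fitted(qx, yy)
      r2 <- sum(fit^2) / ss_tot
      list(r2 = r2, r2_cond = 0, fit = fit)
    } else {
      qz <- qr(z)
      fitz <- qr.fitted(qz, yy)
      yr <- yy - fitz
      xr <- x - qr.fitted(qz, x)
      fit <- qr.fitted(qr(xr), yr)
      list(r2 = sum(fit^2) / ss_tot, r2_cond = sum(fitz^2) / ss_tot, fit = fit)
    }
  }
  obs <- stat(y)
  pseudo_f <- (obs$r2 / p) / ((1 - obs$r2 - obs$r2_cond) / (n - p - q - 1))
  adj <- if (is.null(z)) {
    ezekiel(obs$r2, n, p)
  } else {
    ezekiel(obs$r2 + obs$r2_cond, n, p + q) - ezekiel(obs$r2_cond, n, q)
  }
  eig <- prcomp(obs$fit, center = FALSE)$sdev^2
  eig <- eig[eig > 1e-12]

  p_val <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    if (is.null(z)) {
      f_perm <- vapply(seq_len(n_perm), function(b) {
        s <- stat(y[sample.int(n), , drop = FALSE])
        (s$r2 / p) / ((1 - s$r2 - s$r2_cond) / (n - p - q - 1))
      }, numeric(1))
    } else {
      qz <- qr(z)
      fitz0 <- qr.fitted(qz, y)
      resid0 <- y - fitz0
      f_perm <- vapply(seq_len(n_perm), function(b) {
        yb <- fitz0 + resid0[sample.int(n), , drop = FALSE]
        s <- stat(yb)
        (s$r2 / p) / ((1 - s$r2 - s$r2_cond) / (n - p - q - 1))
      }, numeric(1))
    }
    p_val <- (sum(f_perm >= pseudo_f) + 1) / (n_perm + 1)
  }
  structure(list(r2 = obs$r2, adj_r2 = adj, eigenvalues = eig,
                 pseudo_f = pseudo_f, p = p_val, n_perm = n_perm, seed = seed,
                 df = c(n = n, p = p, q = q)),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA: R2 = %.4f, adjusted R2 = %.4f, pseudo-F = %.3f, p = %.4g\n",
              x$r2, x$adj_r2, x$pseudo_f, x$p))
  invisible(x)
}

#' Permutation-based forward selection of predictors
#'
#' At each step the candidate adding the most adjusted R2 is tested with a
#' marginal permutation F-test (conditioning on the already-selected set)
#' and added if `p <= alpha`. Selection stops when no candidate qualifies
#' or when the cumulative adjusted R2 exceeds the adjusted R2 of the global
#' model (double stopping rule).
#'
#' @param y response matrix.
#' @param x candidate predictor matrix/data frame.
#' @param alpha marginal significance threshold.
#' @param n_perm permutations per test.
#' @param seed seed.
#' @return character vector of selected predictors, in selection order
#'   (may be empty).
#' @export
forward_select <- function(y, x, alpha = 0.05, n_perm = 999, seed = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) < 1) abort("need at least 1 candidate")
  y <- as.matrix(y)
  n <- nrow(y)
  global_adj <- rda(y, x, n_perm = 0)$adj_r2
  selected <- character()
  repeat {
    remaining <- setdiff(colnames(x), selected)
    if (!length(remaining)) break
    cur_adj <- if (length(selected)) {
      rda(y, x[, selected, drop = FALSE], n_perm = 0)$adj_r2
    } else 0
    if (cur_adj > global_adj) break
    gains <- vapply(remaining, function(v) {
      rda(y, x[, c(selected, v), drop = FALSE], n_perm = 0)$adj_r2 - cur_adj
    }, numeric(1))
    best <- remaining[which.max(gains)]
    fit <- if (length(selected)) {
      rda(y, x[, best, drop = FALSE],
          condition = x[, selected, drop = FALSE],
          n_perm = n_perm, seed = derive_seed(seed, length(selected) + 1L))
    } else {
      rda(y, x[, best, drop = FALSE], n_perm = n_perm,
          seed = derive_seed(seed, 1L))
    }
    if (is.na(fit$p) || fit$p > alpha || gains[best] <= 0) break
    selected <- c(selected, best)
    if (rda(y, x[, selected, drop = FALSE], n_perm = 0)$adj_r2 > global_adj) break
  }
  selected
}

#' Partition response variance into environmental and geographic fractions
#'
#' Assembles the standard adjusted-R2 variance partition from three RDA
#' fits (env, geo, env + geo): the exclusive fractions are
#' `env|geo = adj(env+geo) - adj(geo)` and `geo|env = adj(env+geo) -
#' adj(env)`; the confounded fraction is `adj(env) + adj(geo) -
#' adj(env+geo)`, so exclusive + confounded = total explained exactly.
#' The four testable fractions get permutation p-values (the confounded
#' fraction is not testable and gets `NA`).
#'
#' @param y response matrix (populations x SNP frequencies).
#' @param env environmental predictor matrix/data frame.
#' @param geo geographic predictor matrix (e.g. retained MEMs).
#' @param n_perm permutations.
#' @param seed seed.
#' @return tibble of class `partition_table`: `fraction`, `adj_r2`, `p`.
#' @export
variance_partition <- function(y, env, geo, n_perm = 999, seed = 1) {
  env <- as.matrix(env)
  geo <- as.matrix(geo)
  if (is.null(colnames(env))) colnames(env) <- paste0("env", seq_len(ncol(env)))
  if (is.null(colnames(geo))) colnames(geo) <- paste0("geo", seq_len(ncol(geo)))
  if (length(intersect(colnames(env), colnames(geo)))) {
    abort("env and geo sets share variable names")
  }
  y <- as.matrix(y)
  r_env <- rda(y, env, n_perm = n_perm, seed = derive_seed(seed, 1L))
  r_geo <- rda(y, geo, n_perm = n_perm, seed = derive_seed(seed, 2L))
  r_env_geo <- rda(y, env, condition = geo, n_perm = n_perm,
                   seed = derive_seed(seed, 3L))
  r_geo_env <- rda(y, geo, condition = env, n_perm = n_perm,
                   seed = derive_seed(seed, 4L))
  adj_comb <- ezekiel(rda_r2(scale(y, scale = FALSE), cbind(env, geo)),
                      nrow(y), qr(cbind(env, geo))$rank)
  a <- adj_comb - r_geo$adj_r2     # env | geo
  c_ <- adj_comb - r_env$adj_r2    # geo | env
  b <- r_env$adj_r2 + r_geo$adj_r2 - adj_comb
  out <- tibble(
    fraction = c("F ~ env", "F ~ geo", "F ~ env | geo", "F ~ geo | env",
                 "confounded (env + geo)", "total explained",
                 "total unexplained"),
    adj_r2 = c(r_env$adj_r2, r_geo$adj_r2, a, c_, b, adj_comb, 1 - adj_comb),
    p = c(r_env$p, r_geo$p, r_env_geo$p, r_geo_env$p, NA_real_, NA_real_,
          NA_real_)
  )
  class(out) <- c("partition_table", class(out))
  out
}
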