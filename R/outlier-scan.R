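# Two genotype-environment/differentiation outlier scans:
# (a) a PC-based Mahalanobis scan (regress each scaled SNP on the first K
#     genotype PCs, robust Mahalanobis distance of the z-vector, genomic
#     inflation rescaling, chi-square p-values, Benjamini-Hochberg q-values);
# (b) a covariance-standardized environmental rank-correlation scan (whiten
#     population frequencies by the Cholesky factor of a neutral-SNP
#     covariance, Spearman rho against the identically whitened environment,
#     flag the top fraction by |rho|).

#' PC-based Mahalanobis outlier scan
#'
#' Each mean-imputed, scaled SNP column is regressed jointly on the first
#' `K` principal component score vectors, giving K z-scores per SNP. The
#' squared Mahalanobis distance of the z-vector (robust
#' minimum-covariance-determinant estimate of the z covariance) is rescaled
#' by the genomic inflation factor `lambda = median(D2) / median(chi2_K)`
#' and referred to a chi-square distribution with K degrees of freedom;
#' q-values are Benjamini-Hochberg.
#'
#' @param g a [genotype_matrix][new_genotype_matrix].
#' @param K number of principal components (>= 1, < individuals).
#' @param fdr flag SNPs with q-value at or below this level.
#' @param seed seed for the robust covariance subsampling.
#' @return tibble of class `outlier_result`: `snp_id`, `stat` (D2), `p`,
#'   `q`, `outlier`; attributes `K`, `lambda`, `fdr`.
#' @export
pc_mahalanobis_scan <- function(g, K = 3, fdr = 0.01, seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (K < 1 || K >= nrow(g$geno)) abort("`K` must satisfy 1 <= K < individuals")
  x <- impute_scale_geno(g)
  kept <- colnames(x)
  n <- nrow(x)
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  u <- pc$x[, seq_len(K), drop = FALSE]
  fit <- lm.fit(u, x)
  coefs <- matrix(fit$coefficients, nrow = K)
  rss <- colSums(fit$residuals^2)
  sigma2 <- rss / (n - K)
  xtxinv_diag <- 1 / colSums(u^2)      # PC scores are orthogonal
  se <- sqrt(outer(xtxinv_diag, sigma2))
  z <- t(coefs / se)                    # SNPs x K
  finite <- apply(is.finite(z), 1, all)
  z_ok <- z[finite, , drop = FALSE]
  set.seed(seed)
  rc <- MASS::cov.rob(z_ok, method = "mcd")
  d2 <- stats::mahalanobis(z_ok, rc$center, rc$cov)
  lambda <- median(d2) / qchisq(0.5, df = K)
  p <- pchisq(d2 / lambda, df = K, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  out <- tibble(snp_id = kept[finite], stat = d2, p = p, q = q,
                outlier = q <= fdr)
  skipped <- setdiff(g$snps$snp_id, out$snp_id)
  if (length(skipped)) {
    warn(sprintf("skipped %d SNP(s) with undefined test statistics", length(skipped)))
  }
  attr(out, "K") <- K
  attr(out, "lambda") <- lambda
  attr(out, "fdr") <- fdr
  class(out) <- c("outlier_result", class(out))
  out
}

#' Estimate the population covariance of standardized allele frequencies
#'
#' SNP l is standardized as `(p_kl - pbar_l) / sqrt(pbar_l (1 - pbar_l))`
#' with `pbar_l` the across-population mean; the covariance of the
#' population vectors is taken across SNPs. A ridge of `1e-6` is added if
#' the smallest eigenvalue is not positive, guaranteeing a valid Cholesky
#' factor. Supply a designated neutral SNP set (outliers excluded, one SNP
#' per fragment).
#'
#' @param freqs an [allele_freq][new_allele_freq] object (or plain populations x SNPs
#'   matrix) of neutral SNP frequencies.
#' @return object of class `pop_covariance`: `cov`, `chol` (upper
#'   triangular), `populations`, `n_snps`, `ridge`.
#' @export
estimate_pop_covariance <- function(freqs) {
  p <- if (inherits(freqs, "allele_freq")) freqs$freq else as.matrix(freqs)
  if (nrow(p) < 2) abort("need at least 2 populations")
  if (ncol(p) < 50) warn("fewer than 50 neutral SNPs: covariance will be noisy")
  pbar <- colMeans(p, na.rm = TRUE)
  usable <- pbar > 0 & pbar < 1
  s <- sweep(p[, usable, drop = FALSE], 2, pbar[usable], "-")
  s <- sweep(s, 2, sqrt(pbar[usable] * (1 - pbar[usable])), "/")
  s[is.na(s)] <- 0
  cv <- tcrossprod(s) / (ncol(s) - 1)
  ridge <- 0
  if (min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    ridge <- 1e-6
    cv <- cv + diag(ridge, nrow(cv))
  }
  pops <- rownames(p) %||% paste0("pop", seq_len(nrow(p)))
  dimnames(cv) <- list(pops, pops)
  structure(list(cov = cv, chol = chol(cv), populations = pops,
                 n_snps = ncol(s), ridge = ridge),
            class = "pop_covariance")
}

#' Build a population covariance object from an explicit matrix
#'
#' Useful for supplying an identity (no-structure) covariance to
#' [env_correlation_scan()].
#'
#' @param cov symmetric positive-definite populations x populations matrix.
#' @param populations population labels (defaults to the matrix rownames).
#' @return object of class `pop_covariance`.
#' @export
pop_covariance <- function(cov, populations = rownames(cov)) {
  cov <- as.matrix(cov)
  if (is.null(populations)) populations <- paste0("pop", seq_len(nrow(cov)))
  dimnames(cov) <- list(populations, populations)
  structure(list(cov = cov, chol = chol(cov), populations = populations,
                 n_snps = NA_integer_, ridge = 0),
            class = "pop_covariance")
}

whiten <- function(cov_obj, x) {
  # solve L w = x with C = L L' (L = t(chol(C))); identity C returns x
  backsolve(cov_obj$chol, x, transpose = TRUE)
}

#' Covariance-standardized environmental rank-correlation scan
#'
#' Each SNP's centered population-frequency vector and the standardized
#' environmental vector are whitened by the inverse Cholesky factor of the
#' neutral population covariance (removing shared drift structure), and the
#' Spearman rank correlation between the two whitened vectors is the test
#' statistic. The top `top_fraction` of SNPs by |rho| per variable are
#' flagged as putatively adaptive. An optional permutation p-value permutes
#' the whitened environment across populations.
#'
#' @param freqs an [allele_freq][new_allele_freq] object (populations x SNPs).
#' @param cov a [pop_covariance][estimate_pop_covariance] (identity
#'   behaviour: whitening with an identity covariance is exactly centering).
#' @param env environment table (`population` column plus variables), rows
#'   matching the populations of `freqs`.
#' @param vars environmental variables to scan (default: all numeric).
#' @param top_fraction fraction of SNPs flagged per variable, in `(0, 1]`.
#' @param n_perm permutations for the optional p-value (0 = none).
#' @param seed permutation seed.
#' @return tibble of class `outlier_result`: `snp_id`, `variable`, `rho`,
#'   `outlier`, and `p` when `n_perm > 0`.
#' @export
env_correlation_scan <- function(freqs, cov, env, vars = NULL,
                                 top_fraction = 0.05, n_perm = 0, seed = 1) {
  stopifnot(inherits(freqs, "allele_freq"), inherits(cov, "pop_covariance"))
  if (top_fraction <= 0 || top_fraction > 1) abort("`top_fraction` must be in (0, 1]")
  p <- freqs$freq
  if (is.null(rownames(p))) rownames(p) <- freqs$populations
  if (!identical(rownames(p), cov$populations)) {
    if (!setequal(rownames(p), cov$populations)) abort("populations do not match covariance")
    p <- p[cov$populations, , drop = FALSE]
  }
  envx <- env[, setdiff(names(env), c("population", "cell_id")), drop = FALSE]
  envx <- envx[vapply(envx, is.numeric, logical(1))]
  if (!is.null(vars)) envx <- envx[, vars, drop = FALSE]
  if ("population" %in% names(env)) {
    envx <- envx[match(cov$populations, env$population), , drop = FALSE]
  }
  consts <- vapply(envx, function(v) sd(v) == 0, logical(1))
  if (any(consts)) {
    abort(sprintf("constant environmental variable(s): %s",
                  paste(names(envx)[consts], collapse = ", ")))
  }
  pc <- sweep(p, 2, colMeans(p, na.rm = TRUE), "-")
  pc[is.na(pc)] <- 0
  wf <- whiten(cov, pc)                           # populations x SNPs
  res <- purrr::map_dfr(names(envx), function(v) {
    we <- drop(whiten(cov, as.numeric(scale(envx[[v]]))))
    rho <- suppressWarnings(cor(wf, we, method = "spearman"))
    rho <- drop(rho)
    n_flag <- ceiling(top_fraction * sum(!is.na(rho)))
    out <- tibble(snp_id = freqs$snps$snp_id, variable = v, rho = rho,
                  outlier = !is.na(rho) &
                    rank(-abs(rho), ties.method = "first", na.last = "keep") <= n_flag)
    if (n_perm > 0) {
      set.seed(derive_seed(seed, match(v, names(envx))))
      exceed <- rep(0L, length(rho))
      for (b in seq_len(n_perm)) {
        rho_b <- drop(suppressWarnings(cor(wf, we[sample.int(length(we))],
                                           method = "spearman")))
        exceed <- exceed + (abs(rho_b) >= abs(rho))
      }
      out$p <- (exceed + 1) / (n_perm + 1)
    }
    out
  })
  attr(res, "top_fraction") <- top_fraction
  class(res) <- c("outlier_result", class(res))
  res
}
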