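# Per-population diversity statistics and Weir-Cockerham differentiation.
#
# pi at a variant site uses the unbiased diploid estimator
# (2n/(2n-1)) * 2*p*(1-p) with n the genotyped individuals at the site; FIS
# aggregates as 1 - mean(Hobs)/mean(He) (ratio of averages) with Nei's
# unbiased He. Theta is the moment estimator built from the among-population
# (a), among-individual (b) and within-individual (c) variance components,
# combined over loci as sum(a)/sum(a+b+c).

#' Per-population diversity statistics
#'
#' @param g a [genotype_matrix][new_genotype_matrix].
#' @return tibble with one row per population: `population`, `n`
#'   (individuals), `hobs` (mean observed heterozygosity over loci), `pi`
#'   (mean unbiased per-site nucleotide diversity over variant sites), `fis`
#'   (1 - mean Hobs / mean unbiased He; `NA` when every locus is
#'   monomorphic in the population).
#' @export
diversity_per_population <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- sort(unique(g$samples$population))
  purrr::map_dfr(pops, function(pop) {
    sub <- g$geno[g$samples$population == pop, , drop = FALSE]
    n <- colSums(!is.na(sub))
    ok <- n > 0
    p <- colSums(sub, na.rm = TRUE)[ok] / (2 * n[ok])
    hobs_l <- colMeans(sub == 1L, na.rm = TRUE)[ok]
    nn <- n[ok]
    he_l <- (2 * nn / (2 * nn - 1)) * 2 * p * (1 - p)
    he_l[nn < 1] <- NA_real_
    mean_he <- mean(he_l, na.rm = TRUE)
    tibble(
      population = pop, n = nrow(sub),
      hobs = mean(hobs_l),
      pi = mean(he_l, na.rm = TRUE),
      fis = if (isTRUE(mean_he > 0)) 1 - mean(hobs_l) / mean_he else NA_real_
    )
  })
}

# Weir-Cockerham variance components for one locus across r groups.
# n_i: genotyped individuals, p_i: alt frequency, h_i: heterozygote fraction.
# Returns c(a, b, c); NA when fewer than 2 groups have data.
wc_components <- function(n_i, p_i, h_i) {
  use <- n_i > 0 & !is.na(p_i)
  if (sum(use) < 2) return(c(NA_real_, NA_real_, NA_real_))
  n_i <- n_i[use]; p_i <- p_i[use]; h_i <- h_i[use]
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  if (nbar <= 1 || nc <= 0) return(c(NA_real_, NA_real_, NA_real_))
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a, b, cc)
}

# multi-locus theta between two (or more) groups of individuals
wc_theta <- function(geno_list) {
  n_loci <- ncol(geno_list[[1]])
  comp <- vapply(seq_len(n_loci), function(l) {
    n_i <- vapply(geno_list, function(m) sum(!is.na(m[, l])), numeric(1))
    p_i <- vapply(geno_list, function(m) {
      n <- sum(!is.na(m[, l]))
      if (n == 0) NA_real_ else sum(m[, l], na.rm = TRUE) / (2 * n)
    }, numeric(1))
    h_i <- vapply(geno_list, function(m) {
      n <- sum(!is.na(m[, l]))
      if (n == 0) 0 else mean(m[, l] == 1L, na.rm = TRUE)
    }, numeric(1))
    wc_components(n_i, p_i, h_i)
  }, numeric(3))
  a <- comp[1, ]; tot <- colSums(comp)
  keep <- !is.na(tot) & abs(tot) > 0
  if (!any(keep)) return(NA_real_)
  sum(a[keep]) / sum(tot[keep])
}

#' Pairwise Weir-Cockerham FST
#'
#' Multi-locus theta for every pair of populations (or of user-supplied
#' groups such as clusters), with variance components summed over loci.
#'
#' @param g a [genotype_matrix][new_genotype_matrix].
#' @param groups optional named vector or function mapping populations to
#'   groups; defaults to the population labels themselves.
#' @return symmetric matrix of class `fst_matrix` with zero diagonal.
#' @export
pairwise_fst <- function(g, groups = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  grp <- g$samples$population
  if (!is.null(groups)) {
    grp <- unname(groups[g$samples$population])
    if (any(is.na(grp))) abort("`groups` must cover every population")
  }
  labels <- sort(unique(grp))
  if (length(labels) < 2) abort("need at least two populations/groups")
  genos <- lapply(labels, function(lv) g$geno[grp == lv, , drop = FALSE])
  names(genos) <- labels
  for (lv in labels) {
    if (max(colSums(!is.na(genos[[lv]]))) < 2) {
      abort(sprintf("population '%s' has fewer than 2 genotyped individuals at every locus", lv))
    }
  }
  k <- length(labels)
  f <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      th <- wc_theta(genos[c(i, j)])
      f[i, j] <- f[j, i] <- th
    }
  }
  structure(f, class = c("fst_matrix", class(f)))
}

#' Linearize an FST matrix as FST / (1 - FST)
#'
#' Negative estimates are clamped to zero before the transform; an entry
#' equal to 1 (infinite linearized distance) is an error.
#'
#' @param f square FST matrix (e.g. from [pairwise_fst()]).
#' @return distance matrix (class `dist_matrix`) of linearized values.
#' @export
linearize_fst <- function(f) {
  m <- unclass(f)
  if (any(m >= 1, na.rm = TRUE)) {
    abort("FST of 1 cannot be linearized (infinite distance)")
  }
  m <- pmax(m, 0)
  out <- m / (1 - m)
  diag(out) <- 0
  new_dist_matrix(out, metric = "genetic-linearized")
}
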