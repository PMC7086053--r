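# Shared builders and independent oracles for the test suite.

# genotype matrix from a plain matrix (rows = individuals)
make_geno <- function(m, populations, fragment = NULL, pos = NULL,
                      n_alleles = 2L) {
  m <- as.matrix(m)
  n_snp <- ncol(m)
  snps <- tibble::tibble(
    snp_id = colnames(m) %||% sprintf("snp%03d", seq_len(n_snp)),
    fragment = fragment %||% sprintf("frag%03d", seq_len(n_snp)),
    pos = pos %||% rep(1L, n_snp),
    ref = "A", alt = "C",
    n_alleles = rep_len(n_alleles, n_snp)
  )
  rownames(m) <- sprintf("ind%03d", seq_len(nrow(m)))
  colnames(m) <- snps$snp_id
  new_genotype_matrix(m, snps,
                      tibble::tibble(sample_id = rownames(m),
                                     population = populations))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw a random genotype matrix with per-population allele frequencies
random_geno <- function(n_pops, n_per_pop, n_loci, seed, miss = 0) {
  set.seed(seed)
  p <- matrix(runif(n_pops * n_loci, 0.05, 0.95), n_pops, n_loci)
  pops <- rep(sprintf("p%02d", seq_len(n_pops)), each = n_per_pop)
  idx <- rep(seq_len(n_pops), each = n_per_pop)
  g <- matrix(rbinom(length(pops) * n_loci, 2, p[idx, ]), length(pops), n_loci)
  if (miss > 0) g[runif(length(g)) < miss] <- NA_integer_
  make_geno(g, pops)
}

# Independent Weir-Cockerham theta oracle: literal scalar-loop transcription
# of the per-locus variance components a, b, c, combined as sum(a)/sum(a+b+c).
oracle_wc_theta <- function(geno_list) {
  num <- 0; den <- 0
  n_loci <- ncol(geno_list[[1]])
  for (l in seq_len(n_loci)) {
    ns <- c(); ps <- c(); hs <- c()
    for (gm in geno_list) {
      gl <- gm[, l]
      gl <- gl[!is.na(gl)]
      if (length(gl) == 0) next
      ns <- c(ns, length(gl))
      ps <- c(ps, sum(gl) / (2 * length(gl)))
      hs <- c(hs, mean(gl == 1))
    }
    r <- length(ns)
    if (r < 2) next
    nbar <- mean(ns)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    pbar <- sum(ns * ps) / (r * nbar)
    s2 <- sum(ns * (ps - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * hs) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (is.finite(a + b + cc) && abs(a + b + cc) > 0) {
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# insertion-based permutation enumerator, independent of the package's own
enum_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in enum_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# small piecewise-linear single-predictor turnover model F(x) = a * x on [0, 1]
linear_turnover <- function(a = 0.5, var = "x") {
  piecewise_turnover_model(setNames(
    list(list(breaks = c(0, 1), cum = c(0, a))), var))
}

# benchmark synthetic scenario: 17 populations, driver gradient + noise vars
benchmark_sim <- function(seed, n_neutral = 450, n_adaptive = 50, beta = 2,
                          n_per_pop = 12) {
  cfg <- landscape_config(
    n_pops = 17, n_per_pop = n_per_pop, seed = seed,
    variables = dplyr::bind_rows(
      tibble::tibble(name = "E1", kind = "gradient_lon", baseline = 0,
                     amplitude = 1, length = NA),
      tibble::tibble(name = paste0("N", 1:4), kind = "noise", baseline = 0,
                     amplitude = 1, length = 0)
    )
  )
  ls <- generate_landscape(cfg)
  arch <- genetic_architecture(n_neutral = n_neutral, n_adaptive = n_adaptive,
                               beta = beta, driver = "E1",
                               neutral_sd = 0.6, neutral_range = 3,
                               missing_rate = 0.05)
  freqs <- simulate_allele_frequencies(arch, ls$env, ls$coords, seed = seed)
  list(cfg = cfg, landscape = ls, arch = arch, freqs = freqs)
}
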