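test_that("whitening with an identity covariance is exactly centering", {
  set.seed(3)
  f <- matrix(runif(10 * 40), 10, 40,
              dimnames = list(sprintf("p%02d", 1:10), NULL))
  cv <- pop_covariance(diag(10), rownames(f))
  centered <- sweep(f, 2, colMeans(f), "-")
  expect_lt(max(abs(landgf:::whiten(cv, centered) - centered)), 1e-12)
})

test_that("a SNP proportional to the driver has |rho| = 1 under identity covariance", {
  set.seed(9)
  env <- tibble::tibble(population = sprintf("p%02d", 1:12),
                        drv = sort(runif(12)))
  freq <- cbind(0.1 + 0.8 * env$drv, runif(12))
  rownames(freq) <- env$population
  fr <- new_allele_freq(freq, matrix(20, 12, 2),
                        tibble::tibble(snp_id = c("s1", "s2"),
                                       fragment = c("f1", "f2"),
                                       pos = c(1L, 1L)),
                        env$population)
  cv <- pop_covariance(diag(12), env$population)
  res <- env_correlation_scan(fr, cv, env, top_fraction = 0.5)
  expect_equal(res$rho[res$snp_id == "s1"], 1.0, tolerance = 1e-12)
  expect_true(res$outlier[res$snp_id == "s1"])
  # |rho| ranking invariant to a monotone transform of the variable
  env2 <- env; env2$drv <- exp(3 * env2$drv)
  res2 <- env_correlation_scan(fr, cv, env2, top_fraction = 0.5)
  expect_equal(rank(-abs(res$rho)), rank(-abs(res2$rho)))
})

test_that("constant environment is a degenerate-input error", {
  fr <- new_allele_freq(matrix(runif(20), 5, 4), matrix(10, 5, 4),
                        tibble::tibble(snp_id = paste0("s", 1:4),
                                       fragment = paste0("f", 1:4),
                                       pos = rep(1L, 4)),
                        sprintf("p%d", 1:5))
  cv <- pop_covariance(diag(5), sprintf("p%d", 1:5))
  env <- tibble::tibble(population = sprintf("p%d", 1:5), flat = rep(1, 5))
  expect_error(env_correlation_scan(fr, cv, env), "constant")
})

test_that("estimated covariance reflects structure and is always PD", {
  # unstructured populations: off-diagonals are sampling noise around zero
  set.seed(6)
  L <- 3000
  p <- matrix(plogis(qlogis(runif(L, .2, .8))[col(matrix(0, 8, L))] +
                       rnorm(8 * L, 0, .3)), 8, L)
  rownames(p) <- sprintf("p%d", 1:8)
  cv <- estimate_pop_covariance(p)
  offd <- cv$cov[upper.tri(cv$cov)]
  diag_mean <- mean(diag(cv$cov))
  # centering across the 8 populations induces an expected off-diagonal of
  # -diag/(n-1); deviations beyond that are sampling noise
  expect_lt(max(abs(offd + diag_mean / 7)) / diag_mean, 0.08)
  expect_gt(min(eigen(cv$cov, symmetric = TRUE)$values), 0)
  # duplicated population rows give matching covariance rows
  p2 <- rbind(p, p[1, , drop = FALSE] )
  rownames(p2) <- c(rownames(p), "dup")
  cv2 <- estimate_pop_covariance(p2)
  expect_equal(unname(cv2$cov["dup", 2:8]), unname(cv2$cov["p1", 2:8]),
               tolerance = 1e-8)
})

test_that("BH q-values match a brute-force step-up on random p-vectors", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (k in m:1) {
      prev <- min(prev, p[o[k]] * m / k)
      q[o[k]] <- prev
    }
    q
  }
  for (s in 1:5) {
    set.seed(s)
    p <- runif(1000)^2
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-14)
  }
})

test_that("the PC scan is calibrated on pure-drift data", {
  sim <- benchmark_sim(seed = 41, n_neutral = 600, n_adaptive = 0,
                       n_per_pop = 10)
  g <- sample_genotypes(sim$freqs, sim$cfg, sim$arch, seed = 41)
  res <- suppressWarnings(pc_mahalanobis_scan(g, K = 3, fdr = 0.01))
  expect_lte(mean(res$outlier), 0.02)
  expect_gt(attr(res, "lambda"), 0.8)
  expect_lt(attr(res, "lambda"), 1.2)
  # q-values are non-decreasing in p
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
})

test_that("the PC scan finds strong clines among neutral background", {
  sim <- benchmark_sim(seed = 55, n_neutral = 800, n_adaptive = 10, beta = 3,
                       n_per_pop = 10)
  g <- sample_genotypes(sim$freqs, sim$cfg, sim$arch, seed = 55)
  res <- suppressWarnings(pc_mahalanobis_scan(g, K = 3, fdr = 0.01))
  adaptive_ids <- sim$freqs$snps$snp_id[sim$freqs$snps$type == "adaptive"]
  hits <- res$outlier[res$snp_id %in% adaptive_ids]
  expect_gte(mean(hits), 0.8)
})

test_that("whitened scan stays calibrated under strong shared structure", {
  # two blocks of highly covarying populations, no true association:
  # the whitened scan's top-tail should not concentrate on any variable more
  # than the unstructured null expects, while the naive scan inflates
  set.seed(13)
  n_pop <- 12; L <- 400
  block <- rep(1:2, each = 6)
  base <- runif(L, 0.3, 0.7)
  drift <- matrix(rnorm(2 * L, 0, 0.15), 2, L)
  p <- plogis(qlogis(base)[col(matrix(0, n_pop, L))] + drift[block, ] +
                matrix(rnorm(n_pop * L, 0, 0.03), n_pop, L))
  rownames(p) <- sprintf("p%02d", seq_len(n_pop))
  snps <- tibble::tibble(snp_id = sprintf("s%03d", 1:L),
                         fragment = sprintf("f%03d", 1:L), pos = 1L)
  fr <- new_allele_freq(p, matrix(40, n_pop, L), snps, rownames(p))
  cv <- estimate_pop_covariance(p)
  # environment aligned with the block structure but independent of any SNP
  env <- tibble::tibble(population = rownames(p),
                        e = block + rnorm(n_pop, 0, 0.1))
  res_white <- env_correlation_scan(fr, cv, env, top_fraction = 0.05)
  res_naive <- env_correlation_scan(fr, pop_covariance(diag(n_pop), rownames(p)),
                                    env, top_fraction = 0.05)
  # naive scan: structure masquerades as signal, |rho| piles up near 1
  expect_gt(mean(abs(res_naive$rho) > 0.8), mean(abs(res_white$rho) > 0.8))
})
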