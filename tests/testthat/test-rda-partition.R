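line_coords <- function(n) tibble::tibble(population = sprintf("s%02d", 1:n),
                                          lon = seq_len(n), lat = rep(0, n))

test_that("MEM eigenvectors are orthonormal and sinusoidal on a 1-D transect", {
  mem <- mem_basis(line_coords(10), n_perm = 199, seed = 1)
  v <- mem$vectors
  expect_lt(max(abs(crossprod(v) - diag(ncol(v)))), 1e-10)
  # the leading eigenfunction is the broadest spatial wave: strongly rank-
  # correlated with the coordinate (the exact value for this layout is known)
  expect_equal(abs(cor(v[, 1], seq_len(10), method = "spearman")), 0.830,
               tolerance = 0.01)
  # autocorrelation decreases along the eigenvalue ordering
  expect_gt(mem$moran$moran_i[1], mem$moran$moran_i[nrow(mem$moran)])
  expect_error(mem_basis(tibble::tibble(population = c("a", "b", "c", "d"),
                                        lon = c(0, 0, 1, 2),
                                        lat = c(0, 0, 1, 2))),
               "coincident")
})

test_that("MEM construction reproduces the classical PCNM eigenfunctions", {
  skip_if_not_installed("vegan")
  set.seed(9)
  coords <- tibble::tibble(population = sprintf("s%02d", 1:12),
                           lon = runif(12, 0, 10), lat = runif(12, 0, 10))
  mem <- mem_basis(coords, n_perm = 0)
  ref <- vegan::pcnm(dist(cbind(coords$lon, coords$lat)))
  k <- min(ncol(mem$vectors), ncol(ref$vectors))
  for (j in seq_len(k)) {
    agree <- min(max(abs(mem$vectors[, j] - ref$vectors[, j])),
                 max(abs(mem$vectors[, j] + ref$vectors[, j])))
    expect_lt(agree, 1e-6)
  }
})

test_that("significant positive eigenfunctions can be retained", {
  set.seed(2)
  coords <- tibble::tibble(population = sprintf("s%02d", 1:15),
                           lon = runif(15, 0, 10), lat = runif(15, 0, 10))
  mem <- mem_basis(coords, n_perm = 499, seed = 3)
  kept <- mem_keep(mem, n_keep = 3, alpha = 0.2)
  expect_lte(ncol(kept), 3)
  expect_true(all(colnames(kept) %in% mem$moran$mem))
})

test_that("VIF screening matches a leave-one-out regression oracle", {
  set.seed(4)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  x[, 3] <- 0.9 * x[, 1] + 0.4 * rnorm(20)
  res <- vif_screen(x, vif_max = 1000)   # nothing dropped, just VIFs
  oracle <- vapply(1:3, function(j) {
    fit <- stats::lm(x[, j] ~ x[, -j])
    1 / (1 - summary(fit)$r.squared)
  }, numeric(1))
  expect_equal(res$vif$vif, oracle, tolerance = 1e-10)
  # orthogonal columns all kept with VIF ~ 1
  xo <- qr.Q(qr(scale(matrix(rnorm(100), 20, 5), scale = FALSE)))
  colnames(xo) <- paste0("v", 1:5)
  reso <- vif_screen(xo, vif_max = 10)
  expect_equal(reso$kept, colnames(xo))
  expect_true(all(reso$vif$vif < 1.0001))
  # duplicated column: the later-listed one is dropped first
  xd <- cbind(first = x[, 1], second = x[, 1], other = rnorm(20))
  resd <- vif_screen(xd, vif_max = 10)
  expect_equal(resd$dropped[1], "second")
  expect_true("first" %in% resd$kept)
})

test_that("RDA recovers exact and null cases", {
  set.seed(6)
  n <- 20
  x <- matrix(rnorm(n * 2), n, 2)
  b <- matrix(rnorm(2 * 5), 2, 5)
  y_exact <- x %*% b
  fit <- rda(y_exact, x, n_perm = 99, seed = 1)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
  # conditioning on the predictors themselves leaves nothing to explain
  pfit <- rda(y_exact, x, condition = x, n_perm = 0)
  expect_lt(pfit$r2, 1e-10)
  expect_error(rda(y_exact[1:4, ], x[1:4, ], condition = x[1:4, ]),
               "degrees of freedom")
})

test_that("Ezekiel adjustment is the identity at p = 0 and never exceeds R2", {
  expect_equal(landgf:::ezekiel(0.4, 20, 0), 0.4)
  for (r2 in c(0, 0.2, 0.7)) {
    for (p in 1:4) expect_lte(landgf:::ezekiel(r2, 20, p), r2 + 1e-12)
  }
})

test_that("R2 and adjusted R2 agree with vegan on a random instance", {
  skip_if_not_installed("vegan")
  set.seed(8)
  y <- matrix(rnorm(15 * 30), 15, 30)
  x <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(NULL, c("a", "b", "c")))
  ours <- rda(y, x, n_perm = 0)
  ref <- vegan::rda(y ~ a + b + c, data = as.data.frame(x))
  refR2 <- vegan::RsquareAdj(ref)
  expect_equal(ours$r2, refR2$r.squared, tolerance = 1e-10)
  expect_equal(ours$adj_r2, refR2$adj.r.squared, tolerance = 1e-10)
  # partial RDA conditioned fraction matches vegan's partitioning too
  z <- matrix(rnorm(15 * 2), 15, 2, dimnames = list(NULL, c("m1", "m2")))
  ours_p <- rda(y, x, condition = z, n_perm = 0)
  d <- as.data.frame(cbind(x, z))
  ref_p <- vegan::rda(y ~ a + b + c + Condition(m1 + m2), data = d)
  expect_equal(ours_p$r2,
               ref_p$CCA$tot.chi / ref_p$tot.chi, tolerance = 1e-10)
})

test_that("adjusted R2 is unbiased near zero on orthogonal noise", {
  set.seed(10)
  vals <- vapply(1:200, function(i) {
    y <- matrix(rnorm(18 * 10), 18, 10)
    x <- matrix(rnorm(18 * 3), 18, 3)
    rda(y, x, n_perm = 0)$adj_r2
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.015)
})

test_that("forward selection finds the true predictor and resists noise", {
  set.seed(12)
  n <- 25
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("X", 1:5)))
  y <- outer(x[, 1], rnorm(8)) + matrix(rnorm(n * 8, 0, 0.4), n, 8)
  sel <- forward_select(y, x, alpha = 0.05, n_perm = 199, seed = 1)
  expect_equal(sel[1], "X1")
  # a duplicate of X1 adds nothing: exactly one of the pair selected
  xd <- cbind(x, X1dup = x[, 1])
  seld <- forward_select(y, xd, alpha = 0.05, n_perm = 199, seed = 1)
  expect_equal(sum(c("X1", "X1dup") %in% seld), 1L)
})

test_that("forward selection respects the nominal type-I error on noise", {
  set.seed(14)
  any_selected <- vapply(1:60, function(i) {
    y <- matrix(rnorm(15 * 6), 15, 6)
    x <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(NULL, paste0("X", 1:3)))
    length(forward_select(y, x, alpha = 0.05, n_perm = 99, seed = i)) > 0
  }, logical(1))
  # per-step alpha = .05 across 3 candidates: family-wise below ~.14;
  # allow 2 SE over 60 replicates
  expect_lte(mean(any_selected), 0.14 + 2 * sqrt(0.14 * 0.86 / 60))
})

test_that("variance partition recovers constructed orthogonal fractions", {
  set.seed(16)
  n <- 60
  e <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  gmat <- qr.Q(qr(matrix(rnorm(n * 10), n, 10) - e %*% crossprod(e, matrix(rnorm(n * 10), n, 10))))[, 1:2]
  colnames(e) <- c("e1", "e2"); colnames(gmat) <- c("g1", "g2")
  sig_e <- e %*% matrix(rnorm(2 * 12, 0, 3), 2, 12)
  sig_g <- gmat %*% matrix(rnorm(2 * 12, 0, 3), 2, 12)
  noise <- matrix(rnorm(n * 12, 0, 1), n, 12)
  y <- sig_e + sig_g + noise
  pt <- variance_partition(y, e, gmat, n_perm = 99, seed = 1)
  frac <- function(lbl) pt$adj_r2[pt$fraction == lbl]
  true_e <- sum(sig_e^2) / sum(scale(y, scale = FALSE)^2)
  true_g <- sum(sig_g^2) / sum(scale(y, scale = FALSE)^2)
  expect_lt(abs(frac("F ~ env | geo") - true_e), 0.05)
  expect_lt(abs(frac("F ~ geo | env") - true_g), 0.05)
  expect_lt(abs(frac("confounded (env + geo)")), 0.05)
  # ledger identity and untested confounded fraction
  expect_equal(frac("F ~ env | geo") + frac("F ~ geo | env") +
                 frac("confounded (env + geo)"),
               frac("total explained"), tolerance = 1e-10)
  expect_equal(frac("total explained") + frac("total unexplained"), 1,
               tolerance = 1e-12)
  expect_true(is.na(pt$p[pt$fraction == "confounded (env + geo)"]))
})

test_that("identical env and geo sets push everything into the confounded fraction", {
  set.seed(18)
  n <- 40
  shared <- matrix(rnorm(n * 2), n, 2)
  y <- shared %*% matrix(rnorm(2 * 8), 2, 8) + matrix(rnorm(n * 8, 0, 0.8), n, 8)
  e <- shared; colnames(e) <- c("e1", "e2")
  gmat <- shared + matrix(rnorm(n * 2, 0, 1e-6), n, 2)
  colnames(gmat) <- c("g1", "g2")
  pt <- variance_partition(y, e, gmat, n_perm = 0, seed = 1)
  frac <- function(lbl) pt$adj_r2[pt$fraction == lbl]
  expect_lt(abs(frac("F ~ env | geo")), 0.02)
  expect_lt(abs(frac("F ~ geo | env")), 0.02)
  expect_gt(frac("confounded (env + geo)"), 0.2)
})

test_that("permutation p-values are reproducible and bounded below", {
  set.seed(20)
  y <- matrix(rnorm(12 * 6), 12, 6)
  x <- matrix(rnorm(12 * 2), 12, 2)
  f1 <- rda(y, x, n_perm = 99, seed = 3)
  f2 <- rda(y, x, n_perm = 99, seed = 3)
  expect_equal(f1$p, f2$p)
  expect_gte(f1$p, 1 / 100)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(22)
  ps <- vapply(1:500, function(i) {
    y <- matrix(rnorm(14 * 5), 14, 5)
    x <- matrix(rnorm(14 * 2), 14, 2)
    rda(y, x, n_perm = 199, seed = 30000 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})
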