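make_freq <- function(p, pops = sprintf("p%02d", seq_len(nrow(p)))) {
  rownames(p) <- pops
  L <- ncol(p)
  new_allele_freq(p, matrix(40, nrow(p), L),
                  tibble::tibble(snp_id = sprintf("s%03d", seq_len(L)),
                                 fragment = sprintf("f%03d", seq_len(L)),
                                 pos = 1L),
                  pops)
}

test_that("a clean step response concentrates turnover at the step", {
  set.seed(1)
  n <- 30
  env <- tibble::tibble(population = sprintf("p%02d", 1:n),
                        x = seq(0, 1, length.out = n))
  p <- matrix(ifelse(env$x < 0.5, 0.2, 0.8), n, 1)
  fr <- make_freq(p, env$population)
  m <- fit_gf(fr, env, config = gf_config(trees = 300, min_poly_pops = 0,
                                          bins = 50, seed = 2))
  cv <- m$curves$x
  rises <- diff(cv$cum)
  step_bins <- which(cv$breaks[-1] > 0.40 & cv$breaks[-length(cv$breaks)] < 0.60)
  expect_gte(sum(rises[step_bins]) / sum(rises), 0.9)
})

test_that("turnover functions are monotone, start at zero and end at the importance", {
  sim <- benchmark_sim(seed = 61, n_neutral = 60, n_adaptive = 20, beta = 2)
  m <- fit_gf(sim$freqs, sim$landscape$env,
              config = gf_config(trees = 300, min_poly_pops = 0, seed = 1))
  for (v in m$predictors) {
    cv <- m$curves[[v]]
    expect_true(all(diff(cv$cum) >= -1e-12))
    expect_equal(cv$cum[1], 0)
    iv <- unname(m$importance$importance[m$importance$predictor == v])
    expect_equal(max(cv$cum), iv, tolerance = 1e-10)
  }
})

test_that("pure-noise SNPs have non-positive out-of-bag R2 most of the time", {
  set.seed(7)
  n <- 17
  env <- tibble::tibble(population = sprintf("p%02d", 1:n), x = runif(n))
  hit <- vapply(1:20, function(s) {
    p <- matrix(runif(n, 0.2, 0.8), n, 1)
    fr <- make_freq(p, env$population)
    m <- try(fit_gf(fr, env, config = gf_config(trees = 300, min_poly_pops = 0,
                                                seed = s,
                                                positive_only = FALSE)),
             silent = TRUE)
    if (inherits(m, "try-error")) return(TRUE)
    m$snp_stats$r2 <= 0
  }, logical(1))
  expect_gte(mean(hit), 0.7)
})

test_that("fits are reproducible under a fixed seed", {
  sim <- benchmark_sim(seed = 71, n_neutral = 30, n_adaptive = 10, beta = 2)
  m1 <- fit_gf(sim$freqs, sim$landscape$env,
               config = gf_config(trees = 200, min_poly_pops = 0, seed = 5))
  m2 <- fit_gf(sim$freqs, sim$landscape$env,
               config = gf_config(trees = 200, min_poly_pops = 0, seed = 5))
  expect_identical(m1$importance, m2$importance)
  expect_identical(m1$curves, m2$curves)
})

test_that("a duplicated predictor splits importance with its twin", {
  set.seed(19)
  n <- 25
  env <- tibble::tibble(population = sprintf("p%02d", 1:n),
                        a = seq(0, 1, length.out = n),
                        z = runif(n))
  p <- matrix(plogis(qlogis(0.4) + 2.5 * scale(env$a)[, 1] +
                       rnorm(n, 0, 0.15)), n, 20)
  for (j in 2:20) p[, j] <- plogis(qlogis(p[, 1]) + rnorm(n, 0, 0.2))
  fr <- make_freq(p, env$population)
  cfg <- gf_config(trees = 500, min_poly_pops = 0, seed = 3)
  m_single <- fit_gf(fr, env, vars = c("a", "z"), config = cfg)
  env_dup <- env
  env_dup$a2 <- env$a
  m_dup <- fit_gf(fr, env_dup, vars = c("a", "a2", "z"), config = cfg)
  i_single <- m_single$importance$importance[m_single$importance$predictor == "a"]
  i_pair <- sum(m_dup$importance$importance[m_dup$importance$predictor %in% c("a", "a2")])
  expect_lt(abs(i_pair - i_single) / i_single, 0.25)
  halves <- m_dup$importance$importance[m_dup$importance$predictor %in% c("a", "a2")]
  expect_lt(abs(diff(halves)) / i_pair, 0.5)
})

test_that("the driver outranks noise variables across seeds", {
  top <- vapply(1:3, function(s) {
    sim <- benchmark_sim(seed = 400 + s, n_neutral = 90, n_adaptive = 10,
                         beta = 2)
    m <- fit_gf(sim$freqs, sim$landscape$env,
                config = gf_config(trees = 500, min_poly_pops = 0, seed = s))
    m$importance$predictor[1]
  }, character(1))
  expect_true(all(top == "E1"))
})

test_that("greedy correlation pruning follows the documented rule", {
  # chain A-B r=.9, B-C r=.9, A-C r=.1, ranked A > B > C -> keep {A, C}
  set.seed(30)
  n <- 200
  a <- rnorm(n)
  cvec <- rnorm(n) * sqrt(1 - 0.1^2) + 0.1 * a
  b <- local({
    resid <- rnorm(n)
    # build b with cor(a,b)=.9 and cor(b,c)=.9 approximately via projection
    v <- 0.55 * scale(a)[, 1] + 0.55 * scale(cvec)[, 1] + 0.35 * resid
    v
  })
  env <- tibble::tibble(A = a, B = b, C = cvec)
  model <- piecewise_turnover_model(list(
    A = list(breaks = c(0, 1), cum = c(0, 3)),
    B = list(breaks = c(0, 1), cum = c(0, 2)),
    C = list(breaks = c(0, 1), cum = c(0, 1))
  ))
  r_ab <- abs(cor(env$A, env$B)); r_bc <- abs(cor(env$B, env$C))
  r_ac <- abs(cor(env$A, env$C))
  kept <- select_predictors(model, env, r_max = max(r_ac + 0.05, 0.5))
  expect_equal(kept, c("A", "C"))
  # all mutually uncorrelated -> all kept; duplicates -> higher rank kept
  env2 <- tibble::tibble(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  expect_equal(select_predictors(model, env2, r_max = 0.8), c("A", "B", "C"))
  env3 <- tibble::tibble(A = a, B = a, C = rnorm(n))
  expect_equal(select_predictors(model, env3, r_max = 0.8), c("A", "C"))
})

test_that("grid transformation clamps outside the fitted range", {
  model <- linear_turnover(a = 0.5)
  grid <- tibble::tibble(cell_id = 1:5, x = c(-1, 0, 0.5, 1, 7))
  comp <- transform_grid(model, grid)
  expect_equal(unname(comp$comp[, "x"]), c(0, 0, 0.25, 0.5, 0.5))
  # identical climates map to identical compositions
  grid2 <- tibble::tibble(cell_id = 1:2, x = c(0.3, 0.3))
  c2 <- transform_grid(model, grid2)
  expect_equal(c2$comp[1, ], c2$comp[2, ])
  expect_error(transform_grid(model, tibble::tibble(cell_id = 1, y = 1)),
               "lacks predictor")
})

test_that("PCA-RGB map is bounded, degenerate-safe and deterministic", {
  set.seed(44)
  model <- piecewise_turnover_model(list(
    a = list(breaks = c(0, 1), cum = c(0, 1)),
    b = list(breaks = c(0, 1), cum = c(0, 0.5)),
    c = list(breaks = c(0, 1), cum = c(0, 0.2)),
    d = list(breaks = c(0, 1), cum = c(0, 0.1))
  ))
  grid <- tibble::tibble(cell_id = 1:30, lon = runif(30), lat = runif(30),
                         a = runif(30), b = runif(30), c = runif(30),
                         d = runif(30))
  comp <- transform_grid(model, grid)
  rgbm <- pca_rgb(comp)
  for (ch in c("red", "green", "blue")) {
    expect_true(all(rgbm[[ch]] >= 0 & rgbm[[ch]] <= 255))
    expect_true(is.integer(rgbm[[ch]]))
  }
  # uniform composition -> rank 0 -> all channels 128
  gridu <- tibble::tibble(cell_id = 1:4, a = 0.5, b = 0.5, c = 0.5, d = 0.5)
  expect_warning(rgbu <- pca_rgb(transform_grid(model, gridu)), "rank")
  expect_true(all(rgbu$red == 128 & rgbu$green == 128 & rgbu$blue == 128))
})

test_that("out-of-bag R2 behaves like a reference random forest on a smooth signal", {
  skip_if_not_installed("randomForest")
  set.seed(12)
  n <- 40
  X <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- plogis(2 * scale(X[, 1])[, 1] + rnorm(n, 0, 0.3))
  set.seed(1)
  ours <- landgf:::gf_forest_cpp(X, y, 1000L, 1L, 5L)
  set.seed(1)
  ref <- randomForest::randomForest(X, y, ntree = 1000, mtry = 1, nodesize = 5)
  expect_equal(ours$r2, ref$rsq[1000], tolerance = 0.15)
  expect_equal(unname(which.max(ours$importance)),
               unname(which.max(randomForest::importance(ref)[, 1])))
})

test_that("overall importance is stable across forest seeds", {
  sim <- benchmark_sim(seed = 123, n_neutral = 150, n_adaptive = 30, beta = 2)
  imp <- vapply(1:3, function(s) {
    m <- fit_gf(sim$freqs, sim$landscape$env,
                config = gf_config(trees = 1000, min_poly_pops = 0, seed = s))
    m$importance$importance[m$importance$predictor == "E1"]
  }, numeric(1))
  expect_lt((max(imp) - min(imp)) / mean(imp), 0.10)
})
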