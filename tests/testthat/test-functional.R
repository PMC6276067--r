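test_that("smoothing limits behave as the penalty dictates", {
  set.seed(3)
  ages <- 60:100
  y <- -6 + 0.07 * (ages - 60) + 0.3 * sin((ages - 60) / 5)
  Y <- cbind(y, y + 0.1)
  rownames(Y) <- ages

  expect_equal(smooth_log_rates(Y, lambda = 0, monotone = FALSE), Y)

  # very large penalty: per-year fit approaches the least-squares line
  sm <- smooth_log_rates(Y, lambda = 1e6, monotone = FALSE)
  ols <- lm.fit(cbind(1, ages), Y[, 1])$coefficients
  line <- ols[1] + ols[2] * ages
  expect_lt(max(abs(sm[, 1] - line)), 1e-3)

  # monotone projection leaves an increasing curve alone
  yi <- -6 + 0.07 * (ages - 60)
  Yi <- cbind(yi, yi); rownames(Yi) <- ages
  smi <- smooth_log_rates(Yi, lambda = 0, monotone = TRUE, monotone_from = 60)
  expect_lt(max(abs(smi - Yi)), 1e-8)

  expect_error(smooth_log_rates(Y[1:3, ], lambda = 0), "5 ages")
})

test_that("FPCA recovers exact low-rank structure and degenerates sanely", {
  k <- 9; n <- 12
  mu <- seq(-5, -3, length.out = k)
  phi <- sin(seq(0, pi, length.out = k)); phi <- phi / sqrt(sum(phi^2))
  sc <- seq(-2, 2, length.out = n)
  Y <- mu + outer(phi, sc - mean(sc))
  f1 <- fit_fpca(Y, K = 1)
  expect_lt(max(abs(f1$logm_fit - Y)), 1e-10)
  expect_equal(abs(sum(f1$components[, 1] * phi)), 1, tolerance = 1e-10)

  f0 <- fit_fpca(Y, K = 0)
  expect_equal(f0$resid_var, apply(Y, 1, function(r) mean((r - mean(r))^2)),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(fit_fpca(Y, K = 1, weights = rep(0, n)), "zero")
  expect_error(fit_fpca(Y, K = 50), "below")
})

test_that("FPCA matches a brute-force covariance eigensolver", {
  set.seed(7)
  Y <- matrix(rnorm(40), 5, 8)
  f <- fit_fpca(Y, K = 3)
  # oracle: explicit loops
  mu <- rowMeans(Y)
  C <- matrix(0, 5, 5)
  for (t in 1:8) C <- C + (Y[, t] - mu) %o% (Y[, t] - mu)
  C <- C / 8
  eg <- eigen(C, symmetric = TRUE)
  for (j in 1:3) {
    v <- eg$vectors[, j]
    expect_lt(min(max(abs(f$components[, j] - v)),
                  max(abs(f$components[, j] + v))), 1e-10)
  }
  # orthonormality and zero-mean scores
  G <- crossprod(f$components)
  expect_lt(max(abs(G - diag(3))), 1e-8)
  expect_lt(max(abs(colMeans(f$scores))), 1e-8)
})

test_that("integrated squared error equals its brute-force double loop", {
  set.seed(8)
  Y <- matrix(rnorm(60), 6, 10)
  f <- fit_fpca(Y, K = 2)
  ise <- integrated_squared_error(f)
  oracle <- numeric(10)
  for (t in 1:10) {
    sc <- numeric(2)
    for (j in 1:2) sc[j] <- sum((Y[, t] - f$mu) * f$components[, j])
    for (x in 1:6) {
      approx_x <- f$mu[x] + sum(sc * f$components[x, ])
      oracle[t] <- oracle[t] + (Y[x, t] - approx_x)^2
    }
  }
  expect_equal(ise, oracle, tolerance = 1e-12, ignore_attr = TRUE)

  expect_lt(max(integrated_squared_error(f, f$logm_fit)), 1e-18)

  # single-age shift adds exactly delta^2 under a frozen mean-only fit
  f0 <- fit_fpca(Y, K = 0)
  Y2 <- Y; Y2[3, 5] <- Y2[3, 5] + 0.7
  d <- integrated_squared_error(f0, Y2) - integrated_squared_error(f0, Y)
  expect_equal(d[5], 0.7^2 + 2 * 0.7 * (Y[3, 5] - f0$mu[3]), tolerance = 1e-10)
})

test_that("robust refit flags exactly an injected outlier year", {
  truth <- ground_truth()
  s <- simulate_surface(truth, years = 1985:2015, seed = 23)
  out <- inject_outlier_years(s, 2000, 1.0)
  rf <- robust_refit(out, K = 4)
  expect_identical(rf$outlier_years, 2000L)
  expect_equal(rf$year_weights[match(2000, s$years)], 0)

  # zero-weight years have zero influence: deleting them gives the same fit
  Y <- smooth_log_rates(out)
  keep <- rf$year_weights == 1
  ref <- fit_fpca(Y[, keep], K = 4)
  expect_lt(max(abs(rf$mu - ref$mu)), 1e-10)
  expect_lt(max(abs(abs(rf$components) - abs(ref$components))), 1e-10)
})

test_that("clean surfaces are rarely flagged", {
  truth <- ground_truth()
  nflag <- 0
  for (seed in 1:5) {
    s <- simulate_surface(truth, years = 1985:2015, seed = 100 + seed)
    rf <- robust_refit(s, K = 4)
    nflag <- nflag + length(rf$outlier_years)
  }
  expect_lte(nflag, 3)
})

test_that("product-ratio transform is algebraically exact before modeling", {
  truth <- ground_truth()
  ps <- simulate_population_set(truth, years = 1995:2015, seed = 6)
  m1 <- ps[[1]]$rates; m2 <- ps[[2]]$rates
  p <- sqrt(m2 * m1); r <- sqrt(m2 / m1)
  expect_equal(p * r, m2, tolerance = 1e-12)
  expect_equal(p / r, m1, tolerance = 1e-12)
})

test_that("identical populations give a unit ratio function", {
  truth <- ground_truth(sex_gap = 0)
  ps <- simulate_population_set(truth, n_pops = 2, cross_corr = 1,
                                years = 1995:2015, seed = 26,
                                deterministic = TRUE)
  fit <- fit_product_ratio(ps, K = 3)
  # log-ratio model: zero mean and zero scores
  expect_lt(max(abs(fit$sub_models$ratio$mu)), 1e-10)
  expect_lt(max(abs(fit$sub_models$ratio$scores)), 1e-8)
})

test_that("stacked multivariate fit respects symmetry and degenerate cases", {
  truth <- ground_truth(sex_gap = 0)
  ps <- simulate_population_set(truth, n_pops = 2, cross_corr = 1,
                                years = 1995:2015, seed = 27,
                                deterministic = TRUE)
  fit <- fit_multivariate(ps, K = 2)
  k <- length(ps[[1]]$ages)
  c1 <- fit$stacked$components[1:k, 1]
  c2 <- fit$stacked$components[k + 1:k, 1]
  cosim <- sum(c1 * c2) / sqrt(sum(c1^2) * sum(c2^2))
  expect_gt(cosim, 1 - 1e-8)

  # a single population reduces exactly to plain FPCA
  one <- population_set(list(a = ps[[1]]))
  f1 <- fit_multivariate(one, K = 2)
  f2 <- fit_fpca(smooth_log_rates(ps[[1]]), K = 2)
  expect_equal(f1$stacked$logm_fit, f2$logm_fit, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("multilevel decomposition reconstructs and nulls as expected", {
  truth <- ground_truth(sex_gap = 0)
  psI <- simulate_population_set(truth, n_pops = 2, cross_corr = 1,
                                 years = 1985:2015, seed = 28,
                                 deterministic = TRUE)
  fitI <- fit_multilevel(psI, K_common = 2, K_specific = 2, lambda = 0,
                         monotone = FALSE)
  # identical populations: specific deviations are numerically nil
  for (spc in fitI$sub_models$specific)
    expect_lt(max(abs(spc$scores)), 1e-6)

  # additive bookkeeping: mu + R + U + residual == data
  truth2 <- ground_truth()
  ps <- simulate_population_set(truth2, n_pops = 2, cross_corr = 0.5,
                                years = 1985:2015, seed = 29)
  fit <- fit_multilevel(ps, K_common = 2, K_specific = 2)
  sm <- lapply(ps, smooth_log_rates)
  for (j in 1:2) {
    # fitted = mu + common trend + specific trend, exactly
    rebuilt <- fit$mu[[j]] + fit$sub_models$common$logm_fit +
      fit$sub_models$specific[[j]]$logm_fit
    expect_equal(fit$logm_fit[[j]], rebuilt, tolerance = 1e-12,
                 ignore_attr = TRUE)
    resid <- sm[[j]] - fit$logm_fit[[j]]
    expect_equal(fit$logm_fit[[j]] + resid, sm[[j]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(fit_multilevel(ps, K_common = 20, K_specific = 15),
               "below the number of years")
})

test_that("explained variance is non-decreasing in K", {
  truth <- ground_truth()
  s <- simulate_surface(truth, years = 1985:2015, seed = 33)
  Y <- smooth_log_rates(s)
  sse <- sapply(0:5, function(K) sum((fit_fpca(Y, K = K)$logm_fit - Y)^2))
  expect_true(all(diff(sse) <= 1e-9))

  # per-age residual means vanish over retained years
  f <- fit_fpca(Y, K = 3)
  expect_lt(max(abs(rowMeans(Y - f$logm_fit))), 1e-8)
})
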