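test_that("random walk with drift forecasts mean and variance correctly", {
  rw <- rwd_forecast(c(1, 2, 3, 4), h = 2)
  expect_equal(rw$mean, c(5, 6))
  expect_equal(rw$var, c(0, 0))
  expect_error(rwd_forecast(c(1, 2), 1), "at least 3")

  # Monte-Carlo oracle for the h-step conditional variance with
  # estimated drift: refit the drift on each simulated history? No --
  # the stated variance conditions on the data, so simulate future paths
  # with drift drawn from its sampling distribution.
  set.seed(90)
  n <- 30; sigma <- 0.7; drift <- -0.4
  x <- cumsum(c(0, rnorm(n - 1, drift, sigma)))
  rw <- rwd_forecast(x, h = 6)
  B <- 1e5
  dif <- diff(x); dhat <- mean(dif); s2 <- mean((dif - dhat)^2)
  for (h in c(1, 6)) {
    # u = var of future point: innovation part h*s2 plus drift-estimation
    # part h^2 * s2/(n-1); brute-force by simulation
    sim <- rnorm(B, 0, sqrt(s2 * h)) + h * rnorm(B, 0, sqrt(s2 / (n - 1)))
    expect_equal(rw$var[h], var(sim), tolerance = 0.02)
  }
})

test_that("multivariate RWD paths are consistent with the univariate case", {
  set.seed(41)
  x <- cumsum(rnorm(40, -0.3, 0.5))
  paths <- mrwd_forecast(rbind(x), h = 5, n_paths = 1e4, seed = 2)
  rw <- rwd_forecast(x, 5)
  mc_mean <- mean(paths[1, 5, ])
  mc_se <- sd(paths[1, 5, ]) / sqrt(1e4)
  expect_lt(abs(mc_mean - rw$mean[5]), 3 * mc_se)

  # degenerate innovations: every path is the drift line
  y <- seq(0, 10, by = 0.5)
  p2 <- mrwd_forecast(rbind(y, 2 * y), h = 3, n_paths = 50, seed = 3)
  for (b in c(1, 50))
    expect_equal(p2[, , b], cbind(c(10.5, 21), c(11, 22), c(11.5, 23)),
                 tolerance = 1e-10)
  expect_error(mrwd_forecast(matrix(1:6, 3), h = 1), "time points")
})

test_that("cohort index ARIMA selection identifies persistent dynamics", {
  hits <- 0
  for (rep in 1:25) {
    set.seed(200 + rep)
    g <- as.numeric(arima.sim(list(ar = 0.8), n = 200))
    sel <- mortmcs:::select_arima(g)
    if (sel$d == 0 && sel$p >= 1) hits <- hits + 1
  }
  expect_gt(hits / 25, 0.8)
})

test_that("cohort forecasts are centered for white noise and exact for constants", {
  set.seed(77)
  g <- rnorm(120)
  sims <- cohort_forecast(g, h_cohorts = 5, n_paths = 4000, seed = 5)
  m5 <- mean(sims[5, ]); se5 <- sd(sims[5, ]) / sqrt(4000)
  expect_lt(abs(m5), 3 * se5 + 0.05)

  cons <- cohort_forecast(rep(1.3, 30), h_cohorts = 3, n_paths = 10, seed = 1)
  expect_equal(as.vector(cons), rep(1.3, 30), tolerance = 1e-6)
  expect_error(cohort_forecast(rnorm(5), 2), "at least 10")
})

test_that("interval half-widths follow the variance decomposition", {
  # single component, v_x = 0: half-width is exactly z * |b| * sqrt(u)
  s <- lc_exact_surface(k = 8, n = 12)
  fit <- fit_lc_svd(s)
  fit$resid_var[] <- 0
  f <- forecast(fit, h = 4, level = 0.8)
  rw <- rwd_forecast(fit$kappa, 4)
  z <- qnorm(0.9)
  for (h in c(1, 4)) {
    hw <- z * abs(fit$beta) * sqrt(rw$var[h])
    expect_equal(f$upper[, h] - f$point[, h], hw, tolerance = 1e-10)
  }
  # interval widths grow with horizon
  expect_true(all(diff(t(f$upper - f$lower)) >= -1e-12))
})

test_that("zero innovation variance collapses bounds onto the point forecast", {
  s <- lc_exact_surface(k = 8, n = 12)   # kappa is an exact line
  fit <- fit_lc_svd(s)
  f <- forecast(fit, h = 3)
  expect_lt(max(f$upper - f$lower), 1e-8)
  drift <- mean(diff(fit$kappa))
  expect_equal(f$point[, 3],
               fit$alpha + fit$beta * (fit$kappa[12] + 3 * drift),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("GAPC simulation forecasts are reproducible and quantile-stable", {
  truth <- ground_truth()
  s <- simulate_surface(truth, years = 1990:2015, seed = 44)
  fit <- fit_gapc("CBD", s)
  f1 <- forecast(fit, h = 3, n_paths = 500, seed = 9)
  f2 <- forecast(fit, h = 3, n_paths = 500, seed = 9)
  expect_identical(f1$point, f2$point)
  expect_identical(f1$lower, f2$lower)
  expect_identical(f1$upper, f2$upper)
  expect_true(all(f1$lower <= f1$point & f1$point <= f1$upper))

  f4 <- forecast(fit, h = 3, n_paths = 1000, seed = 9)
  expect_lt(max(abs(f4$lower - f1$lower) / abs(f1$lower)), 0.01)
  expect_lt(max(abs(f4$upper - f1$upper) / abs(f1$upper)), 0.01)
})

test_that("cohort-bearing GAPC models forecast through the cohort index", {
  truth <- ground_truth()
  s <- simulate_surface(truth, years = 1985:2015, seed = 45)
  fit <- fit_gapc("M6", s)
  f <- forecast(fit, h = 2, n_paths = 300, seed = 4)
  expect_true(all(is.finite(f$point)))
  expect_true(all(f$lower <= f$point & f$point <= f$upper))
})

test_that("joint-model forecasts return one member per population", {
  truth <- ground_truth()
  ps <- simulate_population_set(truth, years = 1990:2015, seed = 46)
  for (m in c("PRODUCT_RATIO", "MULTIVARIATE", "MULTILEVEL")) {
    fit <- fit_mortality(ps, m, K = 3)
    f <- forecast(fit, h = 2)
    expect_s3_class(f, "mortality_forecast_set")
    expect_identical(names(f), names(ps))
    for (ff in f)
      expect_true(all(ff$lower <= ff$point & ff$point <= ff$upper))
  }
})

test_that("one-step 80% intervals achieve near-nominal empirical coverage", {
  truth <- ground_truth()
  covered <- total <- 0
  for (rep in 1:40) {
    s <- simulate_surface(truth, years = 1975:2016, seed = 500 + rep)
    train <- restrict_years(s, 1975, 2015)
    fit <- fit_lc_svd(train, adjustment = "total_deaths")
    f <- forecast(fit, h = 1, level = 0.8)
    act <- log(log_safe_rates(s))[, "2016"]
    covered <- covered + sum(act >= f$lower[, 1] & act <= f$upper[, 1])
    total <- total + length(act)
  }
  expect_gt(covered / total, 0.70)
  expect_lt(covered / total, 0.90)
})
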