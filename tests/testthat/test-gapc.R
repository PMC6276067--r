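const_tol <- 1e-8

constraint_sums <- function(fit) {
  out <- list()
  spec <- fit$spec
  for (i in seq_along(spec$periods)) {
    if (identical(spec$periods[[i]], "est"))
      out[[paste0("beta", i)]] <- sum(fit$betas[[i]]) - 1
  }
  if (spec$name %in% c("LC_POIS", "RH", "APC"))
    out$kappa1 <- sum(fit$kappas[1, ])
  if (spec$name == "PLAT")
    for (i in 1:3) out[[paste0("kappa", i)]] <- sum(fit$kappas[i, ])
  if (!is.null(fit$gamma)) {
    cc <- as.numeric(names(fit$gamma)); est <- fit$cohort_est
    g <- fit$gamma[est]; c1 <- cc[est]
    deg <- spec$gamma_degree
    out$g0 <- sum(g)
    if (deg >= 1) out$g1 <- sum(c1 * g) / max(abs(c1))
    if (deg >= 2) out$g2 <- sum(c1^2 * g) / max(c1^2)
    if (spec$name == "RH") out$beta0 <- sum(fit$beta0) - 1
  }
  out
}

test_that("Poisson Lee-Carter reproduces a noiseless bilinear surface", {
  s <- lc_exact_surface(k = 10, n = 12)
  fit <- fit_gapc("LC_POIS", s)
  expect_true(fit$converged)
  truth_logm <- log(s$rates)
  expect_lt(max(abs(fit$logm_fit - truth_logm)), 1e-6)
  expect_lt(abs(sum(fit$betas[[1]]) - 1), const_tol)
  expect_lt(abs(sum(fit$kappas[1, ])), const_tol)
})

test_that("every family fit satisfies its identifiability constraints", {
  truth <- ground_truth()
  s <- simulate_surface(truth, years = 1985:2015, seed = 21)
  for (m in c("LC_POIS", "RH", "APC", "CBD", "M6", "M7", "PLAT")) {
    fit <- fit_gapc(m, s, maxit = if (m == "RH") 250 else 500)
    for (v in constraint_sums(fit))
      expect_lt(abs(v), const_tol, label = paste(m, "constraint"))
  }
  fit8 <- fit_gapc("M8", s, xc = 105)
  for (v in constraint_sums(fit8))
    expect_lt(abs(v), const_tol, label = "M8 constraint")
})

test_that("CBD has no static age term and its predictor at mean age is kappa1", {
  truth <- ground_truth()
  s <- simulate_surface(truth, years = 1995:2015, seed = 8)
  fit <- fit_gapc("CBD", s)
  expect_null(fit$alpha)
  expect_equal(nrow(fit$kappas), 2L)
  expect_true(is.finite(fit$deviance))
  xbar_ix <- which(s$ages == round(mean(s$ages)))
  expect_equal(fit$logm_fit[xbar_ix, ], fit$kappas[1, ], tolerance = 1e-10)
})

test_that("APC on cohort-free data estimates a near-null cohort effect", {
  truth <- ground_truth()   # no gamma in the generating process
  s <- simulate_surface(truth, years = 1985:2015, seed = 13)
  fit <- fit_gapc("APC", s)
  # binomial-ish noise scale of log rates at the sparsest cells
  noise <- 1 / sqrt(min(s$deaths[s$deaths > 0]))
  expect_lt(max(abs(fit$gamma[fit$cohort_est])), 5 * noise)
})

test_that("deviance is non-increasing across alternating-update sweeps", {
  truth <- ground_truth()
  s <- simulate_surface(truth, years = 1995:2015, seed = 5)
  for (m in c("LC_POIS", "M7", "PLAT")) {
    fit <- fit_gapc(m, s)
    expect_true(all(diff(fit$deviance_trace) <= 1e-9), label = m)
  }
})

test_that("richer nested models never fit worse", {
  truth <- ground_truth()
  s <- simulate_surface(truth, years = 1985:2015, seed = 17)
  dev <- sapply(c("APC", "RH", "CBD", "M6", "M7"),
                function(m) fit_gapc(m, s)$deviance)
  expect_gte(dev["APC"], dev["RH"] - 1e-6)
  expect_gte(dev["CBD"], dev["M6"] - 1e-6)
  expect_gte(dev["M6"], dev["M7"] - 1e-6)
})

test_that("constraint application is an invariance transformation", {
  truth <- ground_truth()
  s <- simulate_surface(truth, years = 1995:2015, seed = 30)
  fit <- fit_gapc("LC_POIS", s)

  # perturb into an equivalent unconstrained parameterization
  raw <- fit
  raw$betas[[1]] <- fit$betas[[1]] * 2
  raw$kappas[1, ] <- fit$kappas[1, ] / 2 + 5
  raw$alpha <- fit$alpha - fit$betas[[1]] * 2 * 5 / 2
  pred_before <- mortmcs:::gapc_predictor(
    raw[c("alpha", "betas", "kappas", "gamma", "beta0", "xc", "ages")],
    raw$geo, raw$spec)
  back <- apply_constraints(raw)
  pred_after <- mortmcs:::gapc_predictor(
    back[c("alpha", "betas", "kappas", "gamma", "beta0", "xc", "ages")],
    back$geo, back$spec)
  expect_lt(max(abs(pred_before - pred_after)), 1e-10)
  expect_equal(sum(back$betas[[1]]), 1, tolerance = 1e-12)
  expect_equal(sum(back$kappas[1, ]), 0, tolerance = 1e-10)

  # idempotence on an already-constrained fit
  again <- apply_constraints(fit)
  expect_equal(again$betas[[1]], fit$betas[[1]], tolerance = 1e-12)
  expect_equal(again$kappas, fit$kappas, tolerance = 1e-12)

  # fitted death counts unchanged on likelihood cells
  mu_b <- fit$exposures * exp(fit$logm_fit)
  mu_a <- fit$exposures * exp(mortmcs:::gapc_predictor(
    again[c("alpha", "betas", "kappas", "gamma", "beta0", "xc", "ages")],
    again$geo, again$spec))
  rel <- abs(mu_a - mu_b) / pmax(mu_b, 1e-300)
  expect_lt(max(rel[fit$weights > 0]), 1e-9)
})

test_that("a linear-in-cohort effect is absorbed exactly for APC", {
  truth <- ground_truth()
  s <- simulate_surface(truth, years = 1995:2015, seed = 31)
  fit <- fit_gapc("APC", s)
  cc <- as.numeric(names(fit$gamma))
  tampered <- fit
  tampered$gamma <- fit$gamma + ifelse(fit$cohort_est, 0.5 + 0.01 * cc, 0)
  out <- apply_constraints(tampered)
  # the added line vanishes again: gamma returns to the constrained value
  expect_equal(out$gamma[out$cohort_est], fit$gamma[fit$cohort_est],
               tolerance = 1e-8)
  # and a pure line becomes identically zero
  pure <- fit
  pure$gamma <- ifelse(fit$cohort_est, 2 - 0.03 * cc, 0)
  names(pure$gamma) <- names(fit$gamma)
  out2 <- apply_constraints(pure)
  expect_lt(max(abs(out2$gamma[out2$cohort_est])), 1e-10)
})

test_that("sparse cohorts are pinned to zero and excluded from sums", {
  truth <- ground_truth()
  s <- simulate_surface(truth, years = 1995:2015, seed = 32)
  fit <- fit_gapc("M6", s)
  expect_true(all(fit$gamma[!fit$cohort_est] == 0))
  nobs <- fit$geo$cohort_nobs
  expect_true(all(nobs[!fit$cohort_est] < 3))
  expect_true(all(nobs[fit$cohort_est] >= 3))
})

test_that("the M8 constant age is recovered by profile deviance", {
  # generate an exact M8 structure with known xc
  k <- 15; n <- 18
  ages <- 60:(60 + k - 1); years <- 2000:(2000 + n - 1)
  xbar <- mean(ages)
  xc_true <- 80
  kap1 <- seq(-4, -5.5, length.out = n)
  kap2 <- seq(0.05, 0.06, length.out = n)
  cohorts <- (min(years) - max(ages)):(max(years) - min(ages))
  set.seed(40)
  gam <- stats::setNames(0.02 * sin(seq_along(cohorts)), cohorts)
  coh <- outer(-ages, years, `+`)
  eta <- outer(rep(1, k), kap1) + outer(ages - xbar, kap2) +
    (xc_true - ages) * matrix(gam[as.character(coh)], k, n)
  e <- matrix(1e6, k, n)
  s <- mortality_surface(ages, years, exp(eta), deaths = e * exp(eta),
                         exposures = e)
  est <- estimate_xc(s, candidates = c(70, 80, 90, 100))
  expect_equal(est$xc, 80)
  expect_equal(nrow(est$profile), 4L)
  expect_true(all(is.finite(est$profile$deviance)))

  one <- estimate_xc(s, candidates = 85)
  expect_equal(one$xc, 85)
})

test_that("fit_gapc validates its inputs", {
  truth <- ground_truth()
  s <- simulate_surface(truth, years = 2000:2010, seed = 2)
  bare <- mortality_surface(s$ages, s$years, s$rates)
  expect_error(fit_gapc("LC_POIS", bare), "deaths and exposures")
  s2 <- s; s2$deaths[1, 1] <- NA
  expect_error(fit_gapc("LC_POIS", s2), "NA")
})
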