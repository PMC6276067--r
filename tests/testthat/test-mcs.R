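test_that("differentials satisfy their exact identities", {
  set.seed(70)
  L <- matrix(rnorm(30, mean = rep(c(1, 1.2, 0.9), each = 10)), 10, 3)
  colnames(L) <- c("a", "b", "c")
  ds <- compute_differentials(L, B = 500, block_length = 1, seed = 1)
  expect_equal(ds$dbar_pair, -t(ds$dbar_pair), tolerance = 1e-12)
  expect_equal(ds$dbar_dot, rowMeans(ds$dbar_pair), tolerance = 1e-12)
  expect_true(all(ds$var_pair[upper.tri(ds$var_pair)] >= 0))
  expect_true(all(ds$var_dot >= 0))

  # identical loss columns: all differentials zero, EPA accepted exactly
  L2 <- cbind(m1 = L[, 1], m2 = L[, 1])
  ds2 <- compute_differentials(L2, B = 200, block_length = 1, seed = 1)
  expect_equal(max(abs(ds2$dbar_pair)), 0)
  tst <- test_epa(ds2, "Tmax")
  expect_equal(tst$observed, 0)
  expect_equal(tst$p_value, 1)
})

test_that("t statistics match an explicit-loop brute-force computation", {
  set.seed(71)
  L <- matrix(rnorm(30, mean = rep(c(0.5, 0.8, 0.4), each = 10)), 10, 3)
  colnames(L) <- paste0("m", 1:3)
  ds <- compute_differentials(L, B = 1000, block_length = 1, seed = 3)

  m <- 3; N <- 10
  dbar <- matrix(0, m, m)
  for (r in 1:m) for (s in 1:m) {
    acc <- 0
    for (l in 1:N) acc <- acc + (L[l, r] - L[l, s])
    dbar[r, s] <- acc / N
  }
  ddot <- numeric(m)
  for (r in 1:m) {
    acc <- 0
    for (s in 1:m) acc <- acc + dbar[r, s]
    ddot[r] <- acc / m
  }
  expect_equal(ds$dbar_pair, dbar, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ds$dbar_dot, ddot, tolerance = 1e-12, ignore_attr = TRUE)

  # brute-force variances and t statistics from the stored replicates
  bm <- ds$boot_means
  vpair <- matrix(0, m, m); tpair <- matrix(0, m, m)
  for (r in 1:m) for (s in 1:m) if (r != s) {
    devs <- (bm[, r] - bm[, s]) - (mean(L[, r]) - mean(L[, s]))
    vpair[r, s] <- mean(devs^2)
    tpair[r, s] <- dbar[r, s] / sqrt(vpair[r, s])
  }
  vdot <- numeric(m); tdot <- numeric(m)
  for (r in 1:m) {
    devs <- (bm[, r] - rowMeans(bm)) - ddot[r]
    vdot[r] <- mean(devs^2)
    tdot[r] <- ddot[r] / sqrt(vdot[r])
  }
  tst_r <- test_epa(ds, "TR"); tst_m <- test_epa(ds, "Tmax")
  expect_equal(tst_r$t_pair, tpair, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tst_m$t_dot, tdot, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tst_r$observed, max(abs(tpair)), tolerance = 1e-12)
  expect_equal(tst_m$observed, max(tdot), tolerance = 1e-12)
})

test_that("block-bootstrap variance matches the IID closed form", {
  set.seed(72)
  N <- 100
  L <- cbind(a = rnorm(N), b = rnorm(N))
  ds <- compute_differentials(L, B = 5000, block_length = 1, seed = 5)
  d <- L[, 1] - L[, 2]
  expect_equal(ds$var_pair[1, 2],
               mean((d - mean(d))^2) / N, tolerance = 0.05)
})

test_that("block length selection reacts to serial dependence", {
  # white noise: block length 1 most of the time
  ones <- 0
  for (rep in 1:50) {
    set.seed(300 + rep)
    D <- matrix(rnorm(60), 30, 2)
    if (select_block_length(D) == 1L) ones <- ones + 1
  }
  expect_gt(ones / 50, 0.8)

  # strongly autocorrelated differentials: block length at least 2
  big <- 0
  for (rep in 1:50) {
    set.seed(400 + rep)
    D <- matrix(as.numeric(arima.sim(list(ar = 0.9), 200)), 200, 1)
    if (select_block_length(D) >= 2L) big <- big + 1
  }
  expect_gt(big / 50, 0.8)

  expect_identical(select_block_length(matrix(0, 20, 3)), 1L)
})

test_that("a strongly dominated model is detected and eliminated", {
  worst_hits <- 0; pvals <- numeric(20)
  for (rep in 1:20) {
    set.seed(500 + rep)
    L <- matrix(rnorm(20 * 3), 20, 3)
    colnames(L) <- c("good1", "good2", "bad")
    L[, "bad"] <- L[, "bad"] + 10
    ds <- compute_differentials(L, B = 500, block_length = 1, seed = rep)
    tst <- test_epa(ds, "Tmax")
    pvals[rep] <- tst$p_value
    if (tst$worst == "bad") worst_hits <- worst_hits + 1
  }
  expect_gte(worst_hits / 20, 0.95)
  expect_lt(stats::median(pvals), 0.01)
})

test_that("with two models both statistics agree on the worst", {
  agree <- 0
  for (rep in 1:50) {
    set.seed(600 + rep)
    L <- matrix(rnorm(40, mean = rep(c(0, runif(1, 0, 1)), each = 20)), 20, 2)
    colnames(L) <- c("x", "y")
    ds <- compute_differentials(L, B = 300, block_length = 1, seed = rep)
    if (test_epa(ds, "TR")$worst == test_epa(ds, "Tmax")$worst)
      agree <- agree + 1
  }
  expect_equal(agree, 50)
})

test_that("run_mcs handles the degenerate and typical cases", {
  # single model: trivially superior, no tests run
  r1 <- run_mcs(matrix(rnorm(10), ncol = 1,
                       dimnames = list(NULL, "only")), seed = 1)
  expect_identical(r1$superior, "only")
  expect_identical(nrow(r1$eliminated), 0L)

  set.seed(80)
  L <- matrix(rnorm(150), 50, 3)
  colnames(L) <- c("a", "b", "c")
  L[, "c"] <- L[, "c"] + 5
  res <- run_mcs(L, alpha = 0.10, statistic = "Tmax", B = 500, seed = 2)
  expect_false("c" %in% res$superior)
  expect_true(all(c("a", "b") %in% res$superior))
  expect_true(all(sort(c(res$superior, res$eliminated$label)) ==
                    sort(colnames(L))))
  expect_true(all(diff(res$eliminated$mcs_p) >= 0))
})

test_that("superior sets are nested across confidence levels", {
  set.seed(81)
  L <- matrix(rnorm(40 * 5, mean = rep(c(0, 0.15, 0.3, 0.45, 0.6),
                                       each = 40), sd = 1), 40, 5)
  colnames(L) <- paste0("m", 1:5)
  s05 <- run_mcs(L, alpha = 0.05, B = 800, seed = 9)$superior
  s10 <- run_mcs(L, alpha = 0.10, B = 800, seed = 9)$superior
  s25 <- run_mcs(L, alpha = 0.25, B = 800, seed = 9)$superior
  expect_true(all(s10 %in% s05))
  expect_true(all(s25 %in% s10))
})

test_that("results are equivariant under column permutation", {
  set.seed(82)
  L <- matrix(rnorm(120, mean = rep(c(0, 0.5, 1), each = 40)), 40, 3)
  colnames(L) <- c("a", "b", "c")
  perm <- c(3, 1, 2)
  r1 <- run_mcs(L, B = 400, seed = 4)
  r2 <- run_mcs(L[, perm], B = 400, seed = 4)
  expect_setequal(r1$superior, r2$superior)
  expect_identical(r1$eliminated$label, r2$eliminated$label)
  expect_equal(r1$eliminated$step_p, r2$eliminated$step_p, tolerance = 1e-12)
})

test_that("MCS results serialize to JSON", {
  set.seed(83)
  L <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  res <- run_mcs(L, B = 200, seed = 1)
  js <- write_mcs_json(res)
  parsed <- jsonlite::fromJSON(js)
  expect_setequal(parsed$superior, res$superior)
  expect_equal(parsed$alpha, 0.10)
})
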