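# Shared fixtures, all built in code.

# small deterministic rank-1 surface with exact LC structure
lc_exact_surface <- function(k = 8, n = 10, exposure = 1e5) {
  ages <- seq(60, by = 1, length.out = k)
  years <- seq(2000, by = 1, length.out = n)
  alpha <- -6 + 0.08 * (ages - 60)
  beta <- (1 + 0.3 * cos(seq(0, pi, length.out = k)))
  beta <- beta / sum(beta)
  kappa <- seq(2, -2, length.out = n)
  kappa <- kappa - mean(kappa)
  logm <- outer(alpha, rep(1, n)) + outer(beta, kappa)
  e <- matrix(exposure, k, n)
  d <- e * exp(logm)
  s <- mortality_surface(ages, years, exp(logm), deaths = d, exposures = e,
                         label = "exact")
  attr(s, "alpha") <- alpha; attr(s, "beta") <- beta; attr(s, "kappa") <- kappa
  s
}

# tiny HMD-dialect file
write_hmd_fixture <- function(path, rows = NULL) {
  if (is.null(rows)) rows <- c(
    "1975  60  0.01  0.02  0.015",
    "1975  61  0.011 0.021 0.016",
    "1975  62+ 0.5   0.6   0.55",
    "1976  60  0.009 0.019 0.014",
    "1976  61  0.010 0.020 0.015",
    "1976  62+ 0.49  0.59  0.54")
  writeLines(c("Mortality rates (synthetic test fixture)", "", rows), path)
  path
}

default_truth <- function(...) ground_truth(...)
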