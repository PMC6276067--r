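#' Ground truth for synthetic mortality surfaces
#'
#' Defines the generating process for the synthetic fixtures: a
#' log-bilinear age-period structure \eqn{\ln m_{x,t} = \alpha_x + \beta_x
#' \kappa_t (+ \gamma_{t-x})} with a random-walk-with-drift period index,
#' Poisson death counts given exposures, and an optional additive
#' log-rate offset between paired populations (a stylized sex gap).
#'
#' Defaults emulate an old-age mortality panel of the kind national
#' statistical offices publish: ages 60 to 100+ (41 groups), about 41
#' years, a Gompertz-like age profile \eqn{\alpha_x = -9 + 0.09 (x - 60)},
#' a declining period index (drift \eqn{-0.5}, innovation SD 0.3) and
#' exposures of 1e5 person-years per age-year cell.
#'
#' @param ages integer age labels.
#' @param alpha age profile of log rates; defaults to the Gompertz line.
#' @param beta age loadings; normalized to sum to 1.  The default draws
#'   them uniformly on (0, 1) (then normalizes) using `seed`, so the
#'   loading profile is reproducible but not degenerate-constant.
#' @param kappa_drift per-year drift of the period index (negative for
#'   declining mortality).
#' @param kappa_sigma innovation standard deviation of the period index.
#' @param gamma optional cohort effect function of cohort year `t - x`
#'   (a function, or `NULL` for none).
#' @param exposure_scale person-years per age-year cell.
#' @param sex_gap additive log-rate offset applied to the second
#'   population of a pair (males above females by default conventions).
#' @param seed integer seed for the default loading draw.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(ages = 60:100,
                         alpha = -9 + 0.09 * (ages - min(ages)),
                         beta = NULL,
                         kappa_drift = -0.5,
                         kappa_sigma = 0.3,
                         gamma = NULL,
                         exposure_scale = 1e5,
                         sex_gap = 0.3,
                         seed = 1) {
  k <- length(ages)
  if (is.null(beta)) {
    rng <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    b <- stats::runif(k)
    if (!is.null(rng)) assign(".Random.seed", rng, .GlobalEnv)
    beta <- b / sum(b)
  } else {
    beta <- beta / sum(beta)
  }
  stopifnot(length(alpha) == k, length(beta) == k, exposure_scale > 0)
  structure(list(ages = as.integer(ages), alpha = alpha, beta = beta,
                 kappa_drift = kappa_drift, kappa_sigma = kappa_sigma,
                 gamma = gamma, exposure_scale = exposure_scale,
                 sex_gap = sex_gap, seed = seed),
            class = "ground_truth")
}

# Random walk with drift, centered to sum to zero (the usual period-index
# identification), returned with its generating (uncentered) path.
sim_kappa <- function(n, drift, sigma) {
  inc <- drift + stats::rnorm(n, 0, sigma)
  kap <- cumsum(inc)
  kap - mean(kap)
}

surface_from_logm <- function(truth, years, logm, label, deterministic) {
  ages <- truth$ages
  e <- matrix(truth$exposure_scale, length(ages), length(years))
  m_true <- exp(logm)
  if (deterministic) {
    d <- e * m_true
    r <- m_true
  } else {
    d <- matrix(stats::rpois(length(m_true), e * m_true),
                length(ages), length(years))
    r <- derive_rates(d, e)
  }
  mortality_surface(ages, years, r, deaths = d, exposures = e, label = label,
                    open_ended = TRUE)
}

true_log_rates <- function(truth, years, kappa, offset = 0) {
  ages <- truth$ages
  logm <- outer(truth$alpha, rep(1, length(years))) +
    outer(truth$beta, kappa) + offset
  if (!is.null(truth$gamma)) {
    coh <- outer(-ages, years, `+`)        # cohort year t - x
    logm <- logm + matrix(truth$gamma(as.vector(coh)), nrow = length(ages))
  }
  logm
}

#' Simulate one mortality surface with known ground truth
#'
#' @param truth a [ground_truth()] object.
#' @param years calendar years to simulate.
#' @param seed integer seed; the same seed reproduces the surface exactly.
#' @param deterministic if `TRUE`, Poisson sampling is replaced by the
#'   expected counts so that observed rates equal the generating rates
#'   exactly (for exact-recovery tests).
#' @param label population label.
#' @return A [mortality_surface()] with deaths and exposures, carrying the
#'   generating `kappa` path and `truth` in attributes.
#' @export
simulate_surface <- function(truth, years = 1975:2015, seed = 1,
                             deterministic = FALSE, label = "synthetic") {
  stopifnot(inherits(truth, "ground_truth"), length(years) >= 1L)
  set.seed(seed)
  kappa <- if (deterministic && truth$kappa_sigma == 0)
    sim_kappa(length(years), truth$kappa_drift, 0)
  else sim_kappa(length(years), truth$kappa_drift, truth$kappa_sigma)
  logm <- true_log_rates(truth, years, kappa)
  s <- surface_from_logm(truth, years, logm, label, deterministic)
  attr(s, "kappa") <- kappa
  attr(s, "true_log_rates") <- logm
  attr(s, "truth") <- truth
  s
}

#' Simulate a set of correlated populations
#'
#' Each population's period index is a convex mixture of one shared
#' random-walk path and an idiosyncratic path: with `cross_corr = 1` all
#' populations move together; with `cross_corr = 0` they are independent.
#' The second population (and every even-indexed one) receives the
#' `sex_gap` log-rate offset of the ground truth.
#'
#' @param truth a [ground_truth()].
#' @param n_pops number of populations (>= 2).
#' @param cross_corr mixing weight on the common period path, in `[0,1]`.
#' @inheritParams simulate_surface
#' @return A [population_set()]; each member carries its generating
#'   `kappa` in an attribute.
#' @export
simulate_population_set <- function(truth, n_pops = 2, cross_corr = 0.8,
                                    years = 1975:2015, seed = 1,
                                    deterministic = FALSE) {
  stopifnot(n_pops >= 2)
  if (cross_corr < 0 || cross_corr > 1)
    stop("cross_corr must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  n <- length(years)
  common <- sim_kappa(n, truth$kappa_drift, truth$kappa_sigma)
  labs <- if (n_pops == 2) c("female", "male") else paste0("pop", seq_len(n_pops))
  surfaces <- vector("list", n_pops)
  for (j in seq_len(n_pops)) {
    own <- sim_kappa(n, truth$kappa_drift, truth$kappa_sigma)
    kap <- cross_corr * common + (1 - cross_corr) * own
    offset <- if (j %% 2 == 0) truth$sex_gap else 0
    logm <- true_log_rates(truth, years, kap, offset = offset)
    s <- surface_from_logm(truth, years, logm, labs[j], deterministic)
    attr(s, "kappa") <- kap
    attr(s, "true_log_rates") <- logm
    surfaces[[j]] <- s
  }
  ps <- population_set(stats::setNames(surfaces, labs))
  attr(ps, "truth") <- truth
  ps
}

#' Shift selected years' log rates (outlier injection)
#'
#' Adds `shift` to the log rates (and scales deaths accordingly) of the
#' listed years, leaving all other years untouched.  Two calls compose
#' additively.
#'
#' @param surface a [mortality_surface()].
#' @param years years to perturb (must exist in the surface).
#' @param shift additive log-rate bump.
#' @return The perturbed [mortality_surface()].
#' @export
inject_outlier_years <- function(surface, years, shift) {
  if (!length(years)) return(surface)
  ix <- match(years, surface$years)
  if (anyNA(ix))
    stop("unknown year(s): ", paste(years[is.na(ix)], collapse = ", "),
         call. = FALSE)
  r <- surface$rates
  r[, ix] <- r[, ix] * exp(shift)
  d <- surface$deaths
  if (!is.null(d)) d[, ix] <- d[, ix] * exp(shift)
  out <- mortality_surface(surface$ages, surface$years, r, d,
                           surface$exposures, label = surface$label,
                           open_ended = surface$open_ended)
  for (a in c("kappa", "true_log_rates", "truth"))
    attr(out, a) <- attr(surface, a)
  out
}
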