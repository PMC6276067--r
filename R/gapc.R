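#' Specifications of the Poisson age-period-cohort family
#'
#' The generalized age-period-cohort (GAPC) predictor is
#' \deqn{\eta_{x,t} = \alpha_x + \sum_i f_i(x)\,\kappa_t^{(i)} +
#'       g(x)\,\gamma_{t-x},}
#' with death counts \eqn{D_{x,t} \sim} Poisson\eqn{(e_{x,t} e^{\eta_{x,t}})}.
#' Each family member fixes which terms are present, whether the
#' age-modulating functions \eqn{f_i} and the cohort modulator \eqn{g} are
#' estimated nonparametrically or are fixed functions of age, and the
#' identifiability constraint set:
#'
#' * `LC_POIS`: \eqn{\alpha_x + \beta^{(1)}_x \kappa_t};
#'   \eqn{\sum\beta^{(1)} = 1, \sum\kappa = 0}.
#' * `RH`: adds an estimated-modulator cohort term
#'   \eqn{\beta^{(0)}_x\gamma_{t-x}}; also \eqn{\sum\beta^{(0)} = 1,
#'   \sum\gamma = 0}.
#' * `APC`: \eqn{\alpha_x + \kappa_t + \gamma_{t-x}};
#'   \eqn{\sum\kappa = 0, \sum\gamma = 0, \sum c\gamma_c = 0}.
#' * `CBD`: \eqn{\kappa^{(1)}_t + (x-\bar x)\kappa^{(2)}_t}; no constraints.
#' * `M6`: CBD plus \eqn{\gamma_{t-x}}; \eqn{\sum\gamma = 0, \sum c\gamma_c = 0}.
#' * `M7`: adds the quadratic term
#'   \eqn{[(x-\bar x)^2 - \hat\sigma^2_x]\kappa^{(3)}_t}; cohort constrained
#'   to degree 2 (\eqn{\sum\gamma = \sum c\gamma = \sum c^2\gamma = 0}).
#' * `M8`: CBD plus \eqn{(x_c - x)\gamma_{t-x}} with constant \eqn{x_c};
#'   \eqn{\sum\gamma = 0}.
#' * `PLAT`: \eqn{\alpha_x + \kappa^{(1)}_t + (\bar x - x)\kappa^{(2)}_t +
#'   (\bar x - x)^+\kappa^{(3)}_t + \gamma_{t-x}}; all \eqn{\kappa} sums 0
#'   and cohort degree-2 constraints.
#'
#' @param name one of `"LC_POIS"`, `"RH"`, `"APC"`, `"CBD"`, `"M6"`,
#'   `"M7"`, `"M8"`, `"PLAT"`.
#' @return A `gapc_spec` object describing the predictor.
#' @export
gapc_spec <- function(name = c("LC_POIS", "RH", "APC", "CBD", "M6", "M7",
                               "M8", "PLAT")) {
  name <- match.arg(name)
  # period term types: "est" (estimated beta_x), or a fixed function of
  # (x, xbar, sigma2x); cohort: "none", "est" (beta0_x), "one", "xc"
  sp <- switch(name,
    LC_POIS = list(static = TRUE,  periods = list("est"), cohort = "none",
                   gamma_degree = NA_integer_),
    RH      = list(static = TRUE,  periods = list("est"), cohort = "est",
                   gamma_degree = 0L),
    APC     = list(static = TRUE,  periods = list(function(x, xb, s2) rep(1, length(x))),
                   cohort = "one", gamma_degree = 1L),
    CBD     = list(static = FALSE,
                   periods = list(function(x, xb, s2) rep(1, length(x)),
                                  function(x, xb, s2) x - xb),
                   cohort = "none", gamma_degree = NA_integer_),
    M6      = list(static = FALSE,
                   periods = list(function(x, xb, s2) rep(1, length(x)),
                                  function(x, xb, s2) x - xb),
                   cohort = "one", gamma_degree = 1L),
    M7      = list(static = FALSE,
                   periods = list(function(x, xb, s2) rep(1, length(x)),
                                  function(x, xb, s2) x - xb,
                                  function(x, xb, s2) (x - xb)^2 - s2),
                   cohort = "one", gamma_degree = 2L),
    M8      = list(static = FALSE,
                   periods = list(function(x, xb, s2) rep(1, length(x)),
                                  function(x, xb, s2) x - xb),
                   cohort = "xc", gamma_degree = 0L),
    PLAT    = list(static = TRUE,
                   periods = list(function(x, xb, s2) rep(1, length(x)),
                                  function(x, xb, s2) xb - x,
                                  function(x, xb, s2) pmax(xb - x, 0)),
                   cohort = "one", gamma_degree = 2L))
  structure(c(list(name = name), sp), class = "gapc_spec")
}

# ---- internal geometry -----------------------------------------------------

gapc_geometry <- function(spec, ages, years, xc = NULL) {
  k <- length(ages); n <- length(years)
  xbar <- mean(ages)
  s2 <- mean((ages - xbar)^2)
  fmat <- vapply(spec$periods, function(p) {
    if (is.function(p)) p(ages, xbar, s2) else rep(NA_real_, k)
  }, numeric(k))
  fmat <- matrix(fmat, nrow = k)          # NA columns = estimated modulators
  cohorts <- (min(years) - max(ages)):(max(years) - min(ages))
  cmat <- outer(-ages, years, `+`)        # cohort year per cell
  cix <- matrix(match(cmat, cohorts), k, n)
  nobs <- tabulate(cix, nbins = length(cohorts))
  list(k = k, n = n, xbar = xbar, sigma2x = s2, fmat = fmat,
       cohorts = cohorts, cix = cix, cohort_nobs = nobs)
}

gapc_gfun <- function(spec, ages, xc) {
  switch(spec$cohort,
         none = NULL,
         one = rep(1, length(ages)),
         xc = xc - ages,
         est = NA)                        # estimated beta0, handled separately
}

# Predictor matrix eta_{x,t} from a parameter list.
gapc_predictor <- function(par, geo, spec) {
  k <- geo$k; n <- geo$n
  eta <- matrix(0, k, n)
  if (spec$static) eta <- eta + par$alpha
  for (i in seq_along(spec$periods)) {
    f <- if (identical(spec$periods[[i]], "est")) par$betas[[i]] else geo$fmat[, i]
    eta <- eta + outer(f, par$kappas[i, ])
  }
  if (spec$cohort != "none") {
    g <- if (spec$cohort == "est") par$beta0 else gapc_gfun(spec, par$ages, par$xc)
    eta <- eta + g * matrix(par$gamma[geo$cix], k, n)
  }
  eta
}

pois_deviance <- function(d, mu, w) {
  t1 <- ifelse(d > 0, d * log(d / mu), 0)
  2 * sum(w * (t1 - (d - mu)))
}

# ---- constraints -----------------------------------------------------------

#' Apply identifiability constraints by invariance transformations
#'
#' Rescales/translates the parameters of a fitted GAPC model so that the
#' family's constraint set holds exactly, without changing the fitted
#' predictor at any cell that enters the likelihood.  Bilinear terms are
#' normalized by scale/translation; cohort effects have the polynomial of
#' the constraint degree (mean, line, or quadratic in cohort year)
#' transferred into the age and period terms.
#'
#' @param fit a `gapc_fit` from [fit_gapc()].
#' @return The transformed `gapc_fit`; idempotent once constraints hold.
#' @export
apply_constraints <- function(fit) {
  spec <- fit$spec
  par <- fit[c("alpha", "betas", "kappas", "gamma", "beta0", "xc", "ages")]
  par <- constrain_par(par, fit$geo, spec)
  fit[names(par)] <- par
  fit
}

constrain_par <- function(par, geo, spec) {
  ages <- par$ages
  xbar <- geo$xbar; s2 <- geo$sigma2x
  est_coh <- geo$cohort_nobs >= 3L
  cc <- geo$cohorts[est_coh]

  # bilinear period terms with estimated modulators: scale beta to sum 1,
  # center kappa into alpha
  for (i in seq_along(spec$periods)) {
    if (!identical(spec$periods[[i]], "est")) next
    s <- sum(par$betas[[i]])
    if (abs(s) < 1e-12)
      stop("degenerate age modulator: sum(beta) ~ 0", call. = FALSE)
    par$betas[[i]] <- par$betas[[i]] / s
    par$kappas[i, ] <- par$kappas[i, ] * s
    mk <- mean(par$kappas[i, ])
    par$kappas[i, ] <- par$kappas[i, ] - mk
    par$alpha <- par$alpha + par$betas[[i]] * mk
  }

  # cohort term
  if (spec$cohort == "est") {
    s0 <- sum(par$beta0)
    if (abs(s0) < 1e-12)
      stop("degenerate cohort modulator: sum(beta0) ~ 0", call. = FALSE)
    par$beta0 <- par$beta0 / s0
    par$gamma <- par$gamma * s0
    gbar <- mean(par$gamma[est_coh])
    par$gamma[est_coh] <- par$gamma[est_coh] - gbar
    par$alpha <- par$alpha + par$beta0 * gbar
  } else if (spec$cohort %in% c("one", "xc")) {
    deg <- spec$gamma_degree
    X <- outer(cc, 0:deg, `^`)
    co <- qr.coef(qr(X), par$gamma[est_coh])      # OLS => constraint sums vanish
    P <- drop(X %*% co)
    par$gamma[est_coh] <- par$gamma[est_coh] - P
    a <- co[1]; b <- if (deg >= 1) co[2] else 0; q <- if (deg >= 2) co[3] else 0
    ts <- geo$tyears
    if (spec$cohort == "xc") {
      # g(x) = xc - x, degree 0: (xc - x) a = a(xc - xbar) - a (x - xbar)
      par$kappas[1, ] <- par$kappas[1, ] + a * (par$xc - xbar)
      par$kappas[2, ] <- par$kappas[2, ] - a
    } else if (spec$name == "APC") {
      # P(t - x) = (a + b t) - b x
      par$kappas[1, ] <- par$kappas[1, ] + a + b * ts
      par$alpha <- par$alpha - b * ages
      mk <- mean(par$kappas[1, ])
      par$kappas[1, ] <- par$kappas[1, ] - mk
      par$alpha <- par$alpha + mk
    } else if (spec$name == "M6") {
      par$kappas[1, ] <- par$kappas[1, ] + a + b * ts - b * xbar
      par$kappas[2, ] <- par$kappas[2, ] - b
    } else if (spec$name == "M7") {
      par$kappas[1, ] <- par$kappas[1, ] + a + b * ts + q * ts^2 -
        (b + 2 * q * ts) * xbar + q * (xbar^2 + s2)
      par$kappas[2, ] <- par$kappas[2, ] - (b + 2 * q * ts) + 2 * q * xbar
      par$kappas[3, ] <- par$kappas[3, ] + q
    } else if (spec$name == "PLAT") {
      # P(t-x) = [a + bt + qt^2] - (b + 2qt) x + q x^2
      #        = [a + bt + qt^2 - (b + 2qt) xbar] + (b + 2qt)(xbar - x) + q x^2
      par$kappas[1, ] <- par$kappas[1, ] + a + b * ts + q * ts^2 -
        (b + 2 * q * ts) * xbar
      par$kappas[2, ] <- par$kappas[2, ] + b + 2 * q * ts
      par$alpha <- par$alpha + q * ages^2
      for (i in 1:3) {
        mk <- mean(par$kappas[i, ])
        par$kappas[i, ] <- par$kappas[i, ] - mk
        fi <- spec$periods[[i]](ages, xbar, s2)
        par$alpha <- par$alpha + fi * mk
      }
    }
  }
  par
}

# ---- fitting ---------------------------------------------------------------

#' Fit a Poisson generalized age-period-cohort model
#'
#' Maximizes the Poisson log-likelihood of observed death counts with
#' mean \eqn{e_{x,t}\exp(\eta_{x,t})} by alternating damped Newton
#' updates, one parameter vector at a time, applying the identifiability
#' constraints (which leave the predictor unchanged) after every sweep.
#' Cohorts observed fewer than 3 times are pinned to \eqn{\gamma = 0} and
#' their (corner) cells are given zero likelihood weight.
#'
#' @param spec a [gapc_spec()] or model name string.
#' @param surface a [mortality_surface()] with deaths and exposures.
#' @param xc the M8 constant age (required for `"M8"`; see [estimate_xc()]).
#' @param tol convergence tolerance on the relative deviance change.
#' @param maxit iteration cap; `converged = FALSE` when hit.
#' @param gamma_init optional starting values for the cohort effect
#'   (used internally to warm-start Renshaw-Haberman from an APC fit).
#' @return A `gapc_fit` (subclass of `mortality_fit`) with elements
#'   `alpha`, `betas`, `kappas` (one row per period term), `gamma`
#'   (full cohort range, pinned cohorts 0), `deviance`,
#'   `deviance_trace`, `converged`, `iterations`, `logm_fit`.
#' @export
fit_gapc <- function(spec, surface, xc = NULL, tol = 1e-6, maxit = 500,
                     gamma_init = NULL) {
  if (is.character(spec)) spec <- gapc_spec(spec)
  stopifnot(inherits(spec, "gapc_spec"))
  d <- surface$deaths; e <- surface$exposures
  if (is.null(d) || is.null(e))
    stop("fit_gapc needs deaths and exposures on the surface", call. = FALSE)
  if (anyNA(d) || anyNA(e))
    stop("NAs in deaths or exposures", call. = FALSE)
  ages <- surface$ages; years <- surface$years
  geo <- gapc_geometry(spec, ages, years)
  geo$tyears <- years
  k <- geo$k; n <- geo$n
  if (spec$cohort == "xc") {
    if (is.null(xc)) stop("M8 requires the constant age xc", call. = FALSE)
  }

  # likelihood weights: zero for cells of pinned (sparse) cohorts
  w <- matrix(1, k, n)
  if (spec$cohort != "none")
    w[geo$cohort_nobs[geo$cix] < 3L] <- 0

  # Renshaw-Haberman warm start: cohort effect from an APC pre-fit
  if (spec$name == "RH" && is.null(gamma_init)) {
    pre <- fit_gapc("APC", surface, tol = 1e-4, maxit = 200)
    gamma_init <- pre$gamma
  }

  q <- length(spec$periods)
  par <- list(
    ages = ages,
    alpha = if (spec$static)
      log((rowSums(w * d) + 0.5) / pmax(rowSums(w * e), 1e-12)) else rep(0, k),
    betas = lapply(spec$periods, function(p)
      if (identical(p, "est")) rep(1 / k, k) else NULL),
    kappas = matrix(0, q, n),
    gamma = if (is.null(gamma_init)) rep(0, length(geo$cohorts)) else gamma_init,
    beta0 = if (spec$cohort == "est") rep(1 / k, k) else NULL,
    xc = xc)

  est_cells <- w > 0
  dev_of <- function(par) {
    eta <- gapc_predictor(par, geo, spec)
    pois_deviance(d, e * exp(eta), w)
  }

  # damped Newton update of one parameter vector; `amat` is the per-cell
  # multiplier, `group` maps cells to parameter indices (0 = skip)
  update_group <- function(par, field, idx, amat, group, ngroups, dev_cur) {
    eta <- gapc_predictor(par, geo, spec)
    mu <- e * exp(eta)
    num <- tapply_sum(w * amat * (d - mu), group, ngroups)
    den <- tapply_sum(w * amat^2 * mu, group, ngroups)
    step <- ifelse(den > 0, num / den, 0)
    fac <- 1
    for (try in 1:25) {
      cand <- par
      if (is.null(idx)) cand[[field]] <- cand[[field]] + fac * step
      else if (field == "kappas") cand$kappas[idx, ] <- cand$kappas[idx, ] + fac * step
      else cand$betas[[idx]] <- cand$betas[[idx]] + fac * step
      dv <- dev_of(cand)
      if (is.finite(dv) && dv <= dev_cur + 1e-12) return(list(par = cand, dev = dv))
      fac <- fac / 2
    }
    list(par = par, dev = dev_cur)
  }

  row_group <- matrix(rep(seq_len(k), n), k, n)
  col_group <- matrix(rep(seq_len(n), each = k), k, n)
  dev <- dev_of(par)
  trace <- dev
  converged <- FALSE
  it <- 0
  while (it < maxit) {
    it <- it + 1
    dev_prev <- dev
    if (spec$static) {
      up <- update_group(par, "alpha", NULL, matrix(1, k, n), row_group, k, dev)
      par <- up$par; dev <- up$dev
    }
    for (i in seq_len(q)) {
      f <- if (identical(spec$periods[[i]], "est")) par$betas[[i]] else geo$fmat[, i]
      up <- update_group(par, "kappas", i, matrix(f, k, n), col_group, n, dev)
      par <- up$par; dev <- up$dev
      if (identical(spec$periods[[i]], "est")) {
        a <- matrix(par$kappas[i, ], k, n, byrow = TRUE)
        up <- update_group(par, "betas", i, a, row_group, k, dev)
        par <- up$par; dev <- up$dev
      }
    }
    if (spec$cohort != "none") {
      g <- if (spec$cohort == "est") par$beta0 else gapc_gfun(spec, ages, par$xc)
      amat <- matrix(g, k, n)
      cgrp <- ifelse(geo$cohort_nobs[geo$cix] >= 3L, geo$cix, 0L)
      eta <- gapc_predictor(par, geo, spec)
      mu <- e * exp(eta)
      num <- tapply_sum(w * amat * (d - mu), cgrp, length(geo$cohorts))
      den <- tapply_sum(w * amat^2 * mu, cgrp, length(geo$cohorts))
      step <- ifelse(den > 0, num / den, 0)
      fac <- 1
      for (try in 1:25) {
        cand <- par; cand$gamma <- cand$gamma + fac * step
        dv <- dev_of(cand)
        if (is.finite(dv) && dv <= dev + 1e-12) { par <- cand; dev <- dv; break }
        fac <- fac / 2
      }
      if (spec$cohort == "est") {
        a <- matrix(par$gamma[geo$cix], k, n)
        up <- update_group(par, "beta0", NULL, a, row_group, k, dev)
        par <- up$par; dev <- up$dev
      }
    }
    par <- constrain_par(par, geo, spec)   # predictor-invariant
    trace <- c(trace, dev)
    if (abs(dev_prev - dev) < tol * (abs(dev_prev) + 1e-8)) {
      converged <- TRUE
      break
    }
  }

  eta <- gapc_predictor(par, geo, spec)
  fit <- structure(list(
    spec = spec, model = spec$name, label = surface$label,
    ages = ages, years = years, geo = geo,
    xbar = geo$xbar, sigma2x = geo$sigma2x,
    alpha = if (spec$static) par$alpha else NULL,
    betas = par$betas, kappas = par$kappas,
    gamma = if (spec$cohort != "none")
      stats::setNames(par$gamma, geo$cohorts) else NULL,
    cohort_est = geo$cohort_nobs >= 3L,
    beta0 = par$beta0, xc = par$xc,
    deviance = dev, deviance_trace = trace,
    converged = converged, iterations = it,
    logm_fit = eta, weights = w,
    deaths = d, exposures = e),
    class = c("gapc_fit", "mortality_fit"))
  fit$alpha_full <- par$alpha
  fit
}

tapply_sum <- function(x, group, ngroups) {
  keep <- group > 0L
  out <- numeric(ngroups)
  s <- rowsum(as.vector(x)[keep], as.vector(group)[keep])
  out[as.integer(rownames(s))] <- s
  out
}

#' Estimate the M8 constant age by profile deviance
#'
#' Fits the M8 model at each candidate value of the constant \eqn{x_c}
#' and returns the candidate minimizing the Poisson deviance (ties go to
#' the smallest candidate), together with the whole deviance profile.
#'
#' @param surface a [mortality_surface()] with deaths and exposures.
#' @param candidates candidate ages; default is the 20 integer ages above
#'   the top of the data range.
#' @param ... passed to [fit_gapc()].
#' @return List with `xc`, `profile` (data.frame of candidate and
#'   deviance) and `fit` (the winning `gapc_fit`).
#' @export
estimate_xc <- function(surface, candidates = NULL, ...) {
  if (is.null(candidates))
    candidates <- max(surface$ages) + 0:20
  if (!length(candidates)) stop("no candidates", call. = FALSE)
  devs <- rep(NA_real_, length(candidates))
  fits <- vector("list", length(candidates))
  errs <- character(0)
  for (i in seq_along(candidates)) {
    f <- try(fit_gapc("M8", surface, xc = candidates[i], ...), silent = TRUE)
    if (inherits(f, "try-error")) {
      errs <- c(errs, paste0("xc=", candidates[i], ": ", attr(f, "condition")$message))
    } else {
      devs[i] <- f$deviance
      fits[[i]] <- f
    }
  }
  if (all(is.na(devs)))
    stop("all M8 fits failed:\n", paste(errs, collapse = "\n"), call. = FALSE)
  best <- which(devs == min(devs, na.rm = TRUE))[1L]  # ties -> smallest xc
  list(xc = candidates[best],
       profile = data.frame(xc = candidates, deviance = devs),
       fit = fits[[best]])
}
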