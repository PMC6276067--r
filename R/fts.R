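#' Penalized-spline smoothing of log mortality curves
#'
#' Smooths each year's log mortality schedule over age with a penalized
#' cubic smoothing spline ([stats::smooth.spline()] with knots at every
#' age).  `lambda = 0` is the no-penalty limit and returns the input
#' (the interpolating fit at the observation grid); very large `lambda`
#' approaches the least-squares straight line in age.  With
#' `monotone = TRUE` the fitted values are projected onto the
#' non-decreasing cone (pool-adjacent-violators) for ages at and above
#' `monotone_from`, reflecting that old-age mortality increases with age.
#'
#' @param surface a [mortality_surface()] (or a log-rate matrix with the
#'   `ages` argument supplied).
#' @param lambda spline penalty (>= 0); `NULL` selects it per year by
#'   generalized cross-validation.
#' @param monotone enforce a non-decreasing age profile above
#'   `monotone_from`?
#' @param monotone_from first age at which monotonicity is enforced.
#' @param ages age grid when `surface` is a bare matrix.
#' @return The k-by-n matrix of smoothed log rates.
#' @export
smooth_log_rates <- function(surface, lambda = NULL, monotone = TRUE,
                             monotone_from = 65, ages = NULL) {
  wts <- NULL
  if (inherits(surface, "mortality_surface")) {
    lr <- log(log_safe_rates(surface))
    ages <- surface$ages
    # approximate inverse variance of a log death rate is the death
    # count, so sparse (old-age, small-population) cells are downweighted
    if (!is.null(surface$deaths)) wts <- pmax(surface$deaths, 0.5)
  } else {
    lr <- as.matrix(surface)
    if (is.null(ages)) ages <- as.integer(rownames(lr))
  }
  k <- nrow(lr)
  if (k < 5L) stop("need at least 5 ages for spline smoothing", call. = FALSE)
  out <- lr
  if (is.null(lambda) || lambda > 0) {
    for (j in seq_len(ncol(lr))) {
      w <- if (is.null(wts)) rep(1, k) else wts[, j]
      sm <- if (is.null(lambda))
        stats::smooth.spline(ages, lr[, j], w = w, all.knots = TRUE)
      else
        stats::smooth.spline(ages, lr[, j], w = w, all.knots = TRUE,
                             lambda = lambda)
      out[, j] <- stats::predict(sm, ages)$y
    }
  }
  if (monotone) {
    sel <- ages >= monotone_from
    if (sum(sel) >= 2L)
      for (j in seq_len(ncol(out)))
        out[sel, j] <- stats::isoreg(ages[sel], out[sel, j])$yf
  }
  dimnames(out) <- dimnames(lr)
  out
}

#' Functional principal component analysis on a discrete age grid
#'
#' Decomposes log mortality curves as \eqn{\ln m_t(x) \approx \mu(x) +
#' \sum_{k=1}^K \beta_{t,k}\phi_k(x)}: \eqn{\mu} is the (weighted)
#' per-age mean, the \eqn{\phi_k} are the leading eigenvectors of the
#' weighted sample covariance of the centered curves (orthonormal under
#' the discrete inner product with \eqn{\Delta x = 1}), and the scores
#' \eqn{\beta_{t,k}} are projections.  Year weights in \{0, 1\} support
#' the robust variant, where outlying years get weight 0.
#'
#' @param log_rates k-by-n matrix of (smoothed) log rates.
#' @param K number of components (0 = mean-only model).
#' @param weights per-year 0/1 weights; at least one must be 1.
#' @param variant label stored on the fit.
#' @param ages,years grid labels (defaulted from dimnames).
#' @return An `fts_fit` (subclass of `mortality_fit`) with `mu`,
#'   `components` (k-by-K), `scores` (n-by-K), `resid_var` (per-age
#'   weighted mean squared residual \eqn{v_x}), `year_weights`,
#'   `logm_fit`.
#' @export
fit_fpca <- function(log_rates, K = 6, weights = NULL, variant = "FDM",
                     ages = NULL, years = NULL) {
  Y <- as.matrix(log_rates)
  k <- nrow(Y); n <- ncol(Y)
  if (is.null(weights)) weights <- rep(1, n)
  if (!all(weights %in% c(0, 1))) stop("weights must be 0/1", call. = FALSE)
  if (sum(weights) == 0) stop("all year weights are zero", call. = FALSE)
  if (K >= min(k, sum(weights)) && K > 0)
    stop("K must be below min(#ages, #retained years)", call. = FALSE)
  if (is.null(ages)) ages <- if (!is.null(rownames(Y))) as.integer(rownames(Y)) else seq_len(k)
  if (is.null(years)) years <- if (!is.null(colnames(Y))) as.integer(colnames(Y)) else seq_len(n)
  wsum <- sum(weights)
  mu <- drop(Y %*% weights) / wsum
  ctr <- Y - mu
  if (K > 0) {
    cw <- ctr * rep(sqrt(weights), each = k)
    covm <- tcrossprod(cw) / wsum
    eg <- eigen(covm, symmetric = TRUE)
    phi <- eg$vectors[, seq_len(K), drop = FALSE]
    # deterministic sign: largest-magnitude coordinate positive
    for (j in seq_len(K)) {
      pk <- phi[, j]
      if (pk[which.max(abs(pk))] < 0) phi[, j] <- -pk
    }
    scores <- crossprod(ctr, phi)             # n x K, all years
    fitted <- mu + phi %*% t(scores)
    eigvals <- eg$values
  } else {
    phi <- matrix(numeric(0), k, 0)
    scores <- matrix(numeric(0), n, 0)
    fitted <- matrix(mu, k, n)
    eigvals <- numeric(0)
  }
  res <- Y - fitted
  resid_var <- drop((res^2) %*% weights) / wsum
  structure(list(
    model = variant, variant = variant, label = variant,
    ages = ages, years = years,
    mu = mu, components = phi, scores = scores, K = K,
    eigenvalues = eigvals,
    year_weights = weights, resid_var = resid_var,
    logm_fit = fitted, log_rates = Y),
    class = c("fts_fit", "mortality_fit"))
}

#' Integrated squared error of the FPCA approximation, per year
#'
#' \eqn{\mathrm{ISE}_t = \sum_x [\,y_t(x) - \mu(x) - \sum_k
#' \beta_{t,k}\phi_k(x)\,]^2 \Delta x} with \eqn{\Delta x = 1}; the
#' scores are the projections of the supplied curves onto the fit's
#' components.
#'
#' @param fit an `fts_fit`.
#' @param log_rates matrix on the fit's grid; defaults to the fitted data.
#' @return Numeric vector of per-year ISE values.
#' @export
integrated_squared_error <- function(fit, log_rates = fit$log_rates) {
  Y <- as.matrix(log_rates)
  if (nrow(Y) != length(fit$mu))
    stop("grid mismatch between fit and data", call. = FALSE)
  ctr <- Y - fit$mu
  if (fit$K > 0) {
    sc <- crossprod(ctr, fit$components)
    res <- ctr - fit$components %*% t(sc)
  } else res <- ctr
  colSums(res^2)
}

#' Robust functional fit by outlier-year downweighting
#'
#' One-pass robust variant.  A single contaminated year can capture a
#' principal component of its own, so flagging from the in-sample
#' approximation error would let outliers mask themselves; instead, each
#' year's integrated squared error is computed out-of-sample
#' (leave-one-year-out FPCA) and each squared residual is weighted by
#' the cell's death count, the approximate inverse variance of a log
#' rate, making the statistic comparable across years and ages.  The
#' statistic is standardized by a robust scale (its median over the
#' \eqn{\chi^2} median) with the \eqn{\chi^2} degrees of freedom matched
#' robustly (MAD/median moment match); years whose standardized
#' statistic exceeds the upper-`level` \eqn{\chi^2} critical value get
#' weight 0 in the final fit on the smoothed curves.
#'
#' @param surface a [mortality_surface()] (smoothed internally for the
#'   final fit; flagging uses the raw log rates and death counts) or a
#'   bare log-rate matrix (flagging then uses unit weights).
#' @param K number of components.
#' @param level tail probability of the flagging rule, in (0, 1).
#' @param lambda,monotone passed to [smooth_log_rates()].
#' @return An `fts_fit` with `variant = "ROBUST_FDM"`, zero weights on
#'   flagged years, the flagged year labels in `outlier_years`, and the
#'   flag statistic in `outlier_stat`.
#' @export
robust_refit <- function(surface, K = 6, level = 0.999, lambda = NULL,
                         monotone = TRUE) {
  if (inherits(surface, "mortality_surface")) {
    Y <- smooth_log_rates(surface, lambda = lambda, monotone = monotone)
    Yraw <- log(log_safe_rates(surface))
    W <- if (is.null(surface$deaths)) matrix(1, nrow(Y), ncol(Y))
    else pmax(surface$deaths, 0.5)
    yrs <- surface$years; ags <- surface$ages
  } else {
    Y <- Yraw <- as.matrix(surface)
    W <- matrix(1, nrow(Y), ncol(Y))
    yrs <- if (!is.null(colnames(Y))) as.integer(colnames(Y)) else seq_len(ncol(Y))
    ags <- if (!is.null(rownames(Y))) as.integer(rownames(Y)) else seq_len(nrow(Y))
  }
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  n <- ncol(Y)
  st <- numeric(n)
  for (t in seq_len(n)) {
    f <- fit_fpca(Yraw[, -t, drop = FALSE], K = K)
    ctr <- Yraw[, t] - f$mu
    res <- ctr - f$components %*% crossprod(f$components, ctr)
    st[t] <- sum(W[, t] * res^2)
  }
  nu <- match_chisq_df(st)
  scale <- stats::median(st) / stats::qchisq(0.5, nu)
  flagged <- which(st / scale > stats::qchisq(level, nu))
  if (length(flagged) == n)
    stop("all years flagged as outliers; raise `level`", call. = FALSE)
  w <- rep(1, n); w[flagged] <- 0
  fit <- fit_fpca(Y, K = K, weights = w, variant = "ROBUST_FDM",
                  ages = ags, years = yrs)
  fit$outlier_years <- yrs[flagged]
  fit$outlier_stat <- stats::setNames(st, yrs)
  fit$outlier_df <- nu
  fit
}

# robust chi-square df: match the observed MAD/median ratio of the
# statistic to the chi-square family (median and MAD are insensitive to
# the outliers being hunted)
match_chisq_df <- function(st, nu_max = 100L) {
  r_obs <- stats::mad(st, constant = 1) / stats::median(st)
  if (!is.finite(r_obs) || r_obs <= 0) return(nu_max)
  nus <- 2:max(4L, nu_max)
  pp <- stats::ppoints(2001)
  r_th <- vapply(nus, function(nu) {
    qs <- stats::qchisq(pp, nu)
    m <- stats::qchisq(0.5, nu)
    stats::mad(qs, center = m, constant = 1) / m
  }, 0)
  nus[which.min(abs(r_th - r_obs))]
}

#' Coherent two-population fit via product and ratio curves
#'
#' Transforms a pair of populations into the log of the geometric-mean
#' (product) curve \eqn{p_t(x) = \sqrt{m^{(2)}_t m^{(1)}_t}} and the log
#' square-root-ratio curve \eqn{r_t(x) = \sqrt{m^{(2)}_t / m^{(1)}_t}},
#' fits an independent FPCA model to each, and reconstructs the members
#' as \eqn{m^{(2)} = p\,r}, \eqn{m^{(1)} = p/r}.  Because products and
#' ratios are roughly uncorrelated, forecasting them independently keeps
#' the two populations' forecasts coherent (non-diverging ratio).
#'
#' @param popset a two-member [population_set()]; the second member plays
#'   the numerator role (male, in the female/male convention).
#' @param K components per sub-model.
#' @param lambda,monotone smoothing controls, see [smooth_log_rates()].
#' @return An `fts_fit` with `variant = "PRODUCT_RATIO"` and sub-models
#'   in `sub_models$product` / `sub_models$ratio`.
#' @export
fit_product_ratio <- function(popset, K = 6, lambda = NULL, monotone = TRUE) {
  stopifnot(inherits(popset, "population_set"))
  if (length(popset) != 2L)
    stop("product-ratio needs exactly two populations", call. = FALSE)
  l1 <- smooth_log_rates(popset[[1L]], lambda = lambda, monotone = monotone)
  l2 <- smooth_log_rates(popset[[2L]], lambda = lambda, monotone = monotone)
  lp <- (l2 + l1) / 2
  lrat <- (l2 - l1) / 2
  ags <- popset[[1L]]$ages; yrs <- popset[[1L]]$years
  fp <- fit_fpca(lp, K = K, variant = "FDM", ages = ags, years = yrs)
  fr <- fit_fpca(lrat, K = min(K, ncol(lrat) - 1L), variant = "FDM",
                 ages = ags, years = yrs)
  structure(list(
    model = "PRODUCT_RATIO", variant = "PRODUCT_RATIO",
    label = paste(names(popset), collapse = "/"),
    populations = names(popset),
    ages = ags, years = yrs,
    sub_models = list(product = fp, ratio = fr),
    logm_fit = list(fp$logm_fit - fr$logm_fit, fp$logm_fit + fr$logm_fit),
    log_rates = list(l1, l2)),
    class = c("product_ratio_fit", "fts_fit", "mortality_fit"))
}

#' Multivariate functional fit by stacking populations
#'
#' Stacks every population's smoothed log-rate curve for the same year
#' into one long vector of length (number of populations) x (ages) and
#' runs a joint FPCA, so that the leading components capture
#' cross-population covariation directly.
#'
#' @param popset a [population_set()] with at least two members.
#' @param K joint components.
#' @param lambda,monotone smoothing controls.
#' @return An `fts_fit` with `variant = "MULTIVARIATE"`; the stacked fit
#'   is in `stacked`, with block bookkeeping for unstacking.
#' @export
fit_multivariate <- function(popset, K = 6, lambda = NULL, monotone = TRUE) {
  stopifnot(inherits(popset, "population_set"))
  sm <- lapply(popset, smooth_log_rates, lambda = lambda, monotone = monotone)
  Y <- do.call(rbind, sm)
  ags <- popset[[1L]]$ages; yrs <- popset[[1L]]$years
  fit <- fit_fpca(Y, K = K, variant = "MULTIVARIATE",
                  ages = seq_len(nrow(Y)), years = yrs)
  structure(list(
    model = "MULTIVARIATE", variant = "MULTIVARIATE",
    label = paste(names(popset), collapse = "/"),
    populations = names(popset),
    ages = ags, years = yrs, n_blocks = length(popset),
    stacked = fit,
    logm_fit = split_blocks(fit$logm_fit, length(popset)),
    log_rates = sm),
    class = c("multivariate_fit", "fts_fit", "mortality_fit"))
}

split_blocks <- function(Y, nb) {
  k <- nrow(Y) / nb
  lapply(seq_len(nb), function(j) Y[(j - 1) * k + seq_len(k), , drop = FALSE])
}

#' Multilevel functional fit: common trend plus population deviations
#'
#' Decomposes each population's smoothed log mortality curves into a
#' population-specific mean \eqn{\mu^j(x)}, a trend common to all
#' populations \eqn{R_t(x)} (FPCA of the across-population average of the
#' centered curves), a population-specific residual trend
#' \eqn{U_t^j(x)} (per-population FPCA of what remains), and measurement
#' error with per-population variance.
#'
#' @param popset a [population_set()] with at least two members.
#' @param K_common components of the common trend.
#' @param K_specific components of each population-specific trend.
#' @param lambda,monotone smoothing controls.
#' @return An `fts_fit` with `variant = "MULTILEVEL"`, common model in
#'   `sub_models$common` and per-population models in
#'   `sub_models$specific`.
#' @export
fit_multilevel <- function(popset, K_common = 3, K_specific = 3,
                           lambda = NULL, monotone = TRUE) {
  stopifnot(inherits(popset, "population_set"), length(popset) >= 2L)
  n <- length(popset[[1L]]$years)
  if (K_common + K_specific >= n)
    stop("K_common + K_specific must be below the number of years", call. = FALSE)
  sm <- lapply(popset, smooth_log_rates, lambda = lambda, monotone = monotone)
  ags <- popset[[1L]]$ages; yrs <- popset[[1L]]$years
  mus <- lapply(sm, rowMeans)
  ctr <- Map(function(Y, mu) Y - mu, sm, mus)
  agg <- Reduce(`+`, ctr) / length(ctr)
  common <- fit_fpca(agg, K = K_common, variant = "FDM", ages = ags, years = yrs)
  # common$mu ~ 0 by construction; the common trend R_t(x) is the fitted agg
  Rfit <- common$logm_fit
  specific <- Map(function(cj, nm) {
    fit_fpca(cj - Rfit, K = K_specific, variant = "FDM", ages = ags, years = yrs)
  }, ctr, names(popset))
  resid_var <- Map(function(Y, mu, spc) {
    rowMeans((Y - mu - Rfit - spc$logm_fit)^2)
  }, sm, mus, specific)
  structure(list(
    model = "MULTILEVEL", variant = "MULTILEVEL",
    label = paste(names(popset), collapse = "/"),
    populations = names(popset),
    ages = ags, years = yrs,
    mu = mus,
    sub_models = list(common = common, specific = specific),
    resid_var = resid_var,
    logm_fit = Map(function(mu, spc) mu + Rfit + spc$logm_fit, mus, specific),
    log_rates = sm),
    class = c("multilevel_fit", "fts_fit", "mortality_fit"))
}
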