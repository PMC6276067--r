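#' Forecast a fitted mortality model
#'
#' Generic for producing point and interval forecasts of log mortality
#' rates from any `mortality_fit`.  Principal-component based models
#' (Gaussian Lee-Carter, functional variants) extrapolate each score
#' series by a random walk with drift and build Gaussian intervals from
#' the forecast variance plus the model residual variance,
#' \eqn{\mathrm{var}[\ln m_{x,n+h}] \approx \sum_k b_{k,x}^2 u_{k,n+h|n}
#' + v_x}.  Poisson age-period-cohort models simulate joint paths of the
#' period indexes (multivariate random walk with drift) and the cohort
#' index (AIC-selected ARIMA) and read empirical quantiles off the
#' simulated predictor.
#'
#' @param object a fitted model.
#' @param h forecast horizon (years ahead).
#' @param level central prediction-interval coverage \eqn{1-\alpha}
#'   (default 0.8, i.e. \eqn{\alpha = 0.2}).
#' @param ... family-specific arguments (`n_paths`, `seed`).
#' @return A `mortality_forecast` (or a named `mortality_forecast_set`,
#'   one member per population, for joint models): log-rate matrices
#'   `point`, `lower`, `upper` of dimension ages x h.
#' @export
forecast <- function(object, h = 10, level = 0.8, ...) UseMethod("forecast")

#' Random-walk-with-drift forecast of a score series
#'
#' Drift is the mean first difference; the innovation variance is the
#' maximum-likelihood estimate (mean squared deviation of the
#' differences).  The conditional forecast variance includes the
#' drift-estimation term: \eqn{u_{n+h|n} = \hat\sigma^2\, h\, (1 +
#' h/(n-1))} with \eqn{n-1} the number of differences.
#'
#' @param series numeric series of length at least 3.
#' @param h horizon.
#' @return List with `mean` and `var`, each of length `h`.
#' @export
rwd_forecast <- function(series, h) {
  n <- length(series)
  if (n < 3L) stop("random walk with drift needs at least 3 points", call. = FALSE)
  dif <- diff(series)
  drift <- mean(dif)
  sig2 <- mean((dif - drift)^2)
  hh <- seq_len(h)
  list(mean = series[n] + hh * drift,
       var = sig2 * hh * (1 + hh / (n - 1)),
       drift = drift, sigma2 = sig2)
}

#' Joint sample paths of several indexes under a multivariate RWD
#'
#' @param series_matrix q-by-n matrix, one index per row.
#' @param h horizon.
#' @param n_paths number of simulated joint paths.
#' @param seed integer seed.
#' @return Array of dimension `c(q, h, n_paths)`; drift vector and
#'   innovation covariance in attributes.
#' @export
mrwd_forecast <- function(series_matrix, h, n_paths = 1000, seed = 1) {
  X <- rbind(series_matrix)
  q <- nrow(X); n <- ncol(X)
  if (n < q + 2L)
    stop("need at least q + 2 time points for a ", q, "-variate RWD",
         call. = FALSE)
  dif <- X[, -1, drop = FALSE] - X[, -n, drop = FALSE]   # q x (n-1)
  drift <- rowMeans(dif)
  S <- stats::cov(t(dif))
  eg <- eigen(S, symmetric = TRUE)
  rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  set.seed(seed)
  out <- array(0, c(q, h, n_paths))
  last <- X[, n]
  for (b in seq_len(n_paths)) {
    z <- rt %*% matrix(stats::rnorm(q * h), q, h)
    inc <- drift + z
    out[, , b] <- if (h == 1) last + inc
    else last + t(apply(inc, 1, cumsum))
  }
  attr(out, "drift") <- drift
  attr(out, "sigma") <- S
  out
}

# AIC selection over small ARIMA orders; returns working-series model
select_arima <- function(x, pmax = 2, qmax = 2) {
  best <- NULL
  for (d in 0:1) {
    z <- if (d == 0) x else diff(x)
    for (p in 0:pmax) for (q in 0:qmax) {
      fit <- try(suppressWarnings(
        stats::arima(z, order = c(p, 0, q), include.mean = TRUE,
                     method = "ML")), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || stats::AIC(fit) < best$aic)
        best <- list(fit = fit, aic = stats::AIC(fit), p = p, d = d, q = q)
    }
  }
  best
}

#' Forecast the cohort index by an AIC-selected ARIMA model
#'
#' Orders are chosen by AIC over \eqn{p, q \in \{0,1,2\}} and \eqn{d \in
#' \{0,1\}} (differenced fits keep an intercept, i.e. a drift).  Future
#' values are simulated from the ARMA recursion with Gaussian
#' innovations, conditioning on the estimated residual history; when no
#' candidate model can be estimated, a random walk with drift is used
#' and a warning is issued.
#'
#' @param gamma estimated cohort-effect series (>= 10 observations).
#' @param h_cohorts number of future cohorts.
#' @param n_paths simulated paths.
#' @param seed integer seed.
#' @return Matrix `h_cohorts` x `n_paths` of simulated future values;
#'   the selected order is in attribute `order`, the mean forecast in
#'   attribute `mean`.
#' @export
cohort_forecast <- function(gamma, h_cohorts, n_paths = 1000, seed = 1) {
  x <- as.numeric(gamma)
  n <- length(x)
  if (n < 10L) stop("need at least 10 cohort observations", call. = FALSE)
  sel <- select_arima(x)
  set.seed(seed)
  if (is.null(sel)) {
    warning("ARIMA selection failed for the cohort index; using RWD")
    rw <- rwd_forecast(x, h_cohorts)
    sims <- sapply(seq_len(n_paths), function(b)
      x[n] + cumsum(rw$drift + stats::rnorm(h_cohorts, 0, sqrt(rw$sigma2))))
    sims <- matrix(sims, h_cohorts, n_paths)
    attr(sims, "order") <- c(NA, NA, NA)
    attr(sims, "mean") <- rw$mean
    return(sims)
  }
  fit <- sel$fit
  z <- if (sel$d == 0) x else diff(x)
  phi <- if (sel$p > 0) stats::coef(fit)[seq_len(sel$p)] else numeric(0)
  theta <- if (sel$q > 0) stats::coef(fit)[sel$p + seq_len(sel$q)] else numeric(0)
  mu <- stats::coef(fit)[["intercept"]]
  sig <- sqrt(fit$sigma2)
  res <- as.numeric(stats::residuals(fit))
  nz <- length(z)
  sims <- matrix(0, h_cohorts, n_paths)
  means <- numeric(h_cohorts)
  # deterministic mean path (innovations at expectation 0)
  zm <- c(z, numeric(h_cohorts)); em <- c(res, numeric(h_cohorts))
  for (j in seq_len(h_cohorts)) {
    t0 <- nz + j
    ar <- if (sel$p > 0) sum(phi * (zm[t0 - seq_len(sel$p)] - mu)) else 0
    ma <- if (sel$q > 0) sum(theta * em[t0 - seq_len(sel$q)]) else 0
    zm[t0] <- mu + ar + ma
  }
  means_z <- zm[nz + seq_len(h_cohorts)]
  means <- if (sel$d == 0) means_z else x[n] + cumsum(means_z)
  for (b in seq_len(n_paths)) {
    zz <- c(z, numeric(h_cohorts)); ee <- c(res, stats::rnorm(h_cohorts, 0, sig))
    for (j in seq_len(h_cohorts)) {
      t0 <- nz + j
      ar <- if (sel$p > 0) sum(phi * (zz[t0 - seq_len(sel$p)] - mu)) else 0
      ma <- if (sel$q > 0) sum(theta * ee[t0 - seq_len(sel$q)]) else 0
      zz[t0] <- mu + ar + ma + ee[t0]
    }
    zf <- zz[nz + seq_len(h_cohorts)]
    sims[, b] <- if (sel$d == 0) zf else x[n] + cumsum(zf)
  }
  attr(sims, "order") <- c(sel$p, sel$d, sel$q)
  attr(sims, "mean") <- means
  sims
}

new_forecast <- function(model, label, ages, years, point, lower, upper,
                         level, kappa = NULL, seed = NULL) {
  stopifnot(all(lower <= point + 1e-12), all(point <= upper + 1e-12))
  structure(list(model = model, label = label, ages = ages, years = years,
                 horizons = seq_along(years), point = point, lower = lower,
                 upper = upper, level = level, kappa_forecasts = kappa,
                 seed = seed),
            class = "mortality_forecast")
}

#' @export
print.mortality_forecast <- function(x, ...) {
  cat("Forecast from ", x$model, " ('", x$label, "'): ",
      length(x$years), " year(s) ", min(x$years), "-", max(x$years),
      ", ", length(x$ages), " ages, ", 100 * x$level,
      "% intervals\n", sep = "")
  invisible(x)
}

# Gaussian interval assembly for score-driven models:
# point = mu + sum_k phi_k kappa_hat, halfwidth = z sqrt(sum phi^2 u + v)
score_forecast <- function(mu, phi, scores, resid_var, h, level,
                           ages, last_year, model, label) {
  K <- ncol(phi)
  mean_m <- matrix(0, K, h); var_m <- matrix(0, K, h)
  for (k in seq_len(K)) {
    rw <- rwd_forecast(scores[, k], h)
    mean_m[k, ] <- rw$mean; var_m[k, ] <- rw$var
  }
  point <- matrix(mu, length(mu), h)
  if (K > 0) point <- point + phi %*% mean_m
  varf <- matrix(resid_var, length(mu), h)
  if (K > 0) varf <- varf + (phi^2) %*% var_m
  z <- stats::qnorm(1 - (1 - level) / 2)
  hw <- z * sqrt(varf)
  new_forecast(model, label, ages, last_year + seq_len(h),
               point, point - hw, point + hw, level,
               kappa = list(mean = mean_m, var = var_m))
}

#' @rdname forecast
#' @export
forecast.lc_fit <- function(object, h = 10, level = 0.8, ...) {
  score_forecast(object$alpha, cbind(object$beta),
                 cbind(object$kappa), object$resid_var, h, level,
                 object$ages, max(object$years),
                 paste0("LC_SVD[", object$adjustment, "]"), object$label)
}

#' @rdname forecast
#' @export
forecast.fts_fit <- function(object, h = 10, level = 0.8, ...) {
  score_forecast(object$mu, object$components, object$scores,
                 object$resid_var, h, level, object$ages,
                 max(object$years), object$variant, object$label)
}

#' @rdname forecast
#' @export
forecast.product_ratio_fit <- function(object, h = 10, level = 0.8, ...) {
  fp <- forecast(object$sub_models$product, h = h, level = level)
  fr <- forecast(object$sub_models$ratio, h = h, level = level)
  z <- stats::qnorm(1 - (1 - level) / 2)
  vp <- ((fp$upper - fp$point) / z)^2
  vr <- ((fr$upper - fr$point) / z)^2
  hw <- z * sqrt(vp + vr)          # product and ratio treated as independent
  mk <- function(point, nm)
    new_forecast("PRODUCT_RATIO", nm, object$ages, max(object$years) + seq_len(h),
                 point, point - hw, point + hw, level)
  out <- list(mk(fp$point - fr$point, object$populations[1L]),
              mk(fp$point + fr$point, object$populations[2L]))
  names(out) <- object$populations
  structure(out, class = "mortality_forecast_set")
}

#' @rdname forecast
#' @export
forecast.multivariate_fit <- function(object, h = 10, level = 0.8, ...) {
  fs <- forecast(object$stacked, h = h, level = level)
  k <- length(object$ages)
  out <- lapply(seq_len(object$n_blocks), function(j) {
    ix <- (j - 1) * k + seq_len(k)
    new_forecast("MULTIVARIATE", object$populations[j], object$ages,
                 fs$years, fs$point[ix, , drop = FALSE],
                 fs$lower[ix, , drop = FALSE], fs$upper[ix, , drop = FALSE],
                 level)
  })
  names(out) <- object$populations
  structure(out, class = "mortality_forecast_set")
}

#' @rdname forecast
#' @export
forecast.multilevel_fit <- function(object, h = 10, level = 0.8, ...) {
  com <- object$sub_models$common
  fc <- score_forecast(com$mu, com$components, com$scores, com$resid_var * 0,
                       h, level, object$ages, max(object$years),
                       "MULTILEVEL", "common")
  z <- stats::qnorm(1 - (1 - level) / 2)
  vc <- ((fc$upper - fc$point) / z)^2
  out <- Map(function(mu, spc, vres, nm) {
    fsp <- score_forecast(spc$mu, spc$components, spc$scores, spc$resid_var * 0,
                          h, level, object$ages, max(object$years),
                          "MULTILEVEL", nm)
    vs <- ((fsp$upper - fsp$point) / z)^2
    point <- mu + fc$point + fsp$point
    hw <- z * sqrt(vc + vs + vres)
    new_forecast("MULTILEVEL", nm, object$ages, fc$years,
                 point, point - hw, point + hw, level)
  }, object$mu, object$sub_models$specific, object$resid_var,
     object$populations)
  names(out) <- object$populations
  structure(out, class = "mortality_forecast_set")
}

#' @rdname forecast
#' @param n_paths simulated index paths for Poisson age-period-cohort
#'   models.
#' @param seed integer seed for the path simulation.
#' @export
forecast.gapc_fit <- function(object, h = 10, level = 0.8, n_paths = 1000,
                              seed = 1, ...) {
  spec <- object$spec
  geo <- object$geo
  ages <- object$ages; k <- length(ages)
  n <- length(object$years)
  q <- nrow(object$kappas)
  paths <- mrwd_forecast(object$kappas, h, n_paths = n_paths, seed = seed)
  kap_mean <- matrix(attr(paths, "drift"), q, h) ; kap_mean <- object$kappas[, n] +
    t(apply(kap_mean, 1, cumsum))
  if (h == 1) kap_mean <- matrix(object$kappas[, n] + attr(paths, "drift"), q, 1)

  gamma_draw <- NULL; gamma_mean_f <- NULL
  if (spec$cohort != "none") {
    est <- object$cohort_est
    coh <- geo$cohorts
    gam_est <- object$gamma[est]
    last_est <- max(coh[est])
    need_max <- max(object$years) + h - min(ages)
    n_future <- max(0L, need_max - last_est)
    if (n_future > 0) {
      gamma_draw <- cohort_forecast(gam_est, n_future, n_paths = n_paths,
                                    seed = seed + 1L)
      gamma_mean_f <- attr(gamma_draw, "mean")
    }
    gamma_at <- function(cc, b = NULL) {
      # value of the cohort index at cohort year cc for path b (NULL = mean)
      out <- numeric(length(cc))
      inr <- cc <= last_est
      ix <- match(cc[inr], coh)
      out[inr] <- ifelse(!is.na(ix) & est[ix], object$gamma[ix], 0)
      fut <- which(!inr)
      if (length(fut)) {
        step <- cc[fut] - last_est
        out[fut] <- if (is.null(b)) gamma_mean_f[step] else gamma_draw[step, b]
      }
      out
    }
  }

  g <- switch(spec$cohort, none = NULL, est = object$beta0,
              one = rep(1, k), xc = object$xc - ages)
  eta_from <- function(kap_h, gamma_vals_by_h) {
    # kap_h: q x h; returns k x h predictor
    eta <- matrix(0, k, h)
    if (spec$static) eta <- eta + object$alpha
    for (i in seq_len(q)) {
      f <- if (identical(spec$periods[[i]], "est")) object$betas[[i]] else geo$fmat[, i]
      eta <- eta + outer(f, kap_h[i, ])
    }
    if (!is.null(g)) eta <- eta + g * gamma_vals_by_h
    eta
  }
  gamma_block <- function(b) {
    if (spec$cohort == "none") return(NULL)
    sapply(seq_len(h), function(j)
      gamma_at(max(object$years) + j - ages, b))
  }
  point <- eta_from(kap_mean, if (spec$cohort == "none") NULL else gamma_block(NULL))
  sims <- array(0, c(k, h, n_paths))
  for (b in seq_len(n_paths)) {
    kb <- matrix(paths[, , b], q, h)
    sims[, , b] <- eta_from(kb, if (spec$cohort == "none") NULL else gamma_block(b))
  }
  alp <- 1 - level
  lower <- apply(sims, c(1, 2), stats::quantile, probs = alp / 2)
  upper <- apply(sims, c(1, 2), stats::quantile, probs = 1 - alp / 2)
  lower <- matrix(lower, k, h); upper <- matrix(upper, k, h)
  new_forecast(spec$name, object$label, ages, max(object$years) + seq_len(h),
               point, pmin(lower, point), pmax(upper, point), level,
               kappa = list(mean = kap_mean), seed = seed)
}

#' Long-format view of a forecast
#'
#' @param x a `mortality_forecast`.
#' @param ... unused.
#' @return data.frame with columns
#'   `model,population,year,age,point,lower,upper,level`.
#' @export
as.data.frame.mortality_forecast <- function(x, ...) {
  k <- length(x$ages); H <- length(x$years)
  data.frame(model = x$model, population = x$label,
             year = rep(x$years, each = k), age = rep(x$ages, H),
             point = as.vector(x$point), lower = as.vector(x$lower),
             upper = as.vector(x$upper), level = x$level)
}
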