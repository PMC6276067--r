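#' Lee-Carter fit under Gaussian errors (SVD)
#'
#' Fits \eqn{\ln m_{x,t} = \alpha_x + \beta_x \kappa_t + \varepsilon_{x,t}}
#' by taking \eqn{\alpha_x} as the per-age mean of log rates and
#' \eqn{(\beta, \kappa)} from the rank-1 singular value decomposition of
#' the centered log-rate matrix, normalized so that \eqn{\sum_x \beta_x =
#' 1} and \eqn{\sum_t \kappa_t = 0}.  Dividing by the signed sum of the
#' first left singular vector resolves the arbitrary SVD sign
#' deterministically, so runs are reproducible across SVD
#' implementations; with the predominantly positive loadings of real
#' mortality surfaces this leaves \eqn{\kappa} with non-positive drift
#' when mortality declines.
#'
#' @param surface a [mortality_surface()] with positive rates (the
#'   zero-cell half-minimum rule of [log_safe_rates()] is applied first).
#' @param adjustment period-index adjustment to apply immediately; see
#'   [adjust_kappa()].
#' @return An `lc_fit` (subclass of `mortality_fit`) with `alpha`, `beta`,
#'   `kappa`, `residuals` (\eqn{\ln m - \alpha - \beta\kappa}),
#'   `resid_var` (per-age mean squared residual \eqn{v_x}), `adjustment`.
#' @export
fit_lc_svd <- function(surface,
                       adjustment = c("none", "total_deaths", "e0",
                                      "deaths_distribution")) {
  adjustment <- match.arg(adjustment)
  if (length(surface$years) < 2L)
    stop("need at least 2 years for a Lee-Carter fit", call. = FALSE)
  lr <- log(log_safe_rates(surface))
  if (anyNA(lr)) stop("missing rates in surface", call. = FALSE)
  alpha <- rowMeans(lr)
  ctr <- lr - alpha
  sv <- svd(ctr, nu = 1, nv = 1)
  beta <- sv$u[, 1]; kappa <- sv$v[, 1] * sv$d[1]
  s <- sum(beta)
  if (abs(s) < 1e-12) {
    # degenerate loading (e.g. constant surface); fall back to uniform
    beta <- rep(1 / length(beta), length(beta))
    kappa <- rep(0, length(kappa))
  } else {
    # dividing by the (signed) sum resolves the SVD sign ambiguity
    # deterministically: sum(beta) = 1 always, and with predominantly
    # positive loadings a declining-mortality surface yields a kappa
    # with non-positive drift
    kappa <- kappa * s
    beta <- beta / s
  }
  kappa <- kappa - mean(kappa)
  fit <- structure(list(
    model = "LC_SVD", label = surface$label,
    ages = surface$ages, years = surface$years,
    alpha = alpha, beta = beta, kappa = kappa,
    adjustment = "none",
    log_rates = lr),
    class = c("lc_fit", "mortality_fit"))
  fit <- lc_finalize(fit)
  if (adjustment != "none") fit <- adjust_kappa(fit, surface, adjustment)
  fit
}

lc_finalize <- function(fit) {
  fitted <- fit$alpha + outer(fit$beta, fit$kappa)
  fit$logm_fit <- fitted
  fit$residuals <- fit$log_rates - fitted
  fit$resid_var <- rowMeans(fit$residuals^2)
  fit
}

#' Adjust the Lee-Carter period index
#'
#' Re-estimates each year's \eqn{\kappa_t}, holding \eqn{\alpha} and
#' \eqn{\beta} fixed, to match a demographic target:
#'
#' * `"total_deaths"`: solve \eqn{\sum_x e_{x,t} e^{\alpha_x + \beta_x
#'   \kappa_t} = \sum_x d_{x,t}} by bracketed root finding;
#' * `"e0"`: match the period life expectancy at the youngest age of the
#'   fitted rate schedule to the observed one;
#' * `"deaths_distribution"`: minimize the Poisson deviance of the
#'   observed death counts against \eqn{e_{x,t} e^{\alpha_x+\beta_x\kappa_t}};
#' * `"none"`: identity.
#'
#' The adjusted index is *not* re-centered: its level is meaningful.
#'
#' @param fit an `lc_fit`.
#' @param surface the surface the fit came from (deaths/exposures needed
#'   for the death-based targets).
#' @param method the adjustment target.
#' @return The `lc_fit` with adjusted `kappa`, refreshed fitted values
#'   and residual variances, and `adjustment` recorded.
#' @export
adjust_kappa <- function(fit, surface,
                         method = c("none", "total_deaths", "e0",
                                    "deaths_distribution")) {
  method <- match.arg(method)
  if (method == "none") return(fit)
  d <- surface$deaths; e <- surface$exposures
  if (method %in% c("total_deaths", "deaths_distribution") &&
      (is.null(d) || is.null(e)))
    stop("adjustment '", method, "' needs deaths and exposures", call. = FALSE)
  kap <- fit$kappa
  # estimated loadings can change sign across ages, so the target
  # function need not be monotone in kappa; scan the +/- 50 window for
  # the sign change nearest the current index value, then polish
  scan_root <- function(f, centre, what, year) {
    grid <- centre + seq(-50, 50, by = 1)
    vals <- vapply(grid, f, 0)
    sgn <- which(vals[-1] * vals[-length(vals)] <= 0)
    if (!length(sgn))
      stop(what, " root not bracketed within kappa +/- 50 (year ", year,
           ")", call. = FALSE)
    near <- sgn[which.min(abs(grid[sgn] - centre))]
    stats::uniroot(f, c(grid[near], grid[near + 1]), tol = 1e-10)$root
  }
  for (j in seq_along(kap)) {
    kap[j] <- switch(method,
      total_deaths = {
        obs <- sum(d[, j])
        f <- function(kk) sum(e[, j] * exp(fit$alpha + fit$beta * kk)) - obs
        scan_root(f, kap[j], "total-deaths", surface$years[j])
      },
      e0 = {
        obs <- period_life_expectancy(surface$rates[, j], surface$ages,
                                      open_ended = surface$open_ended)
        f <- function(kk) period_life_expectancy(
          exp(fit$alpha + fit$beta * kk), surface$ages,
          open_ended = surface$open_ended) - obs
        scan_root(f, kap[j], "life-expectancy", surface$years[j])
      },
      deaths_distribution = {
        f <- function(kk) {
          mu <- e[, j] * exp(fit$alpha + fit$beta * kk)
          2 * sum(ifelse(d[, j] > 0, d[, j] * log(d[, j] / mu), 0) -
                    (d[, j] - mu))
        }
        stats::optimize(f, c(kap[j] - 50, kap[j] + 50), tol = 1e-10)$minimum
      })
  }
  fit$kappa <- kap
  fit$adjustment <- method
  lc_finalize(fit)
}

#' Period life expectancy from a rate schedule
#'
#' Standard period lifetable with mid-interval deaths (\eqn{a_x = 0.5})
#' and, when the last age group is open-ended, a closing person-years
#' term \eqn{L_{last} = l_{last}/m_{last}}.  Returns the expected
#' remaining years of life at the first (youngest) supplied age.
#'
#' @param rates positive central death rates, one per age.
#' @param ages the corresponding ages (used only for a length check).
#' @param open_ended is the last group open-ended?
#' @return Remaining life expectancy at the first age, in years.
#' @export
period_life_expectancy <- function(rates, ages = seq_along(rates),
                                   open_ended = TRUE) {
  if (length(rates) != length(ages))
    stop("rates and ages lengths differ", call. = FALSE)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("rates must be positive for the lifetable", call. = FALSE)
  k <- length(rates)
  q <- rates / (1 + 0.5 * rates)          # a_x = 0.5
  q <- pmin(q, 1)
  l <- cumprod(c(1, 1 - q[-k]))
  dx <- l * q
  L <- l - 0.5 * dx
  if (open_ended) L[k] <- l[k] / rates[k] else L[k] <- l[k] - 0.5 * dx[k]
  sum(L) / l[1]
}
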