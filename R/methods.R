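#' @export
print.mortality_fit <- function(x, ...) {
  cat("Mortality model ", x$model, " ('", x$label, "')\n", sep = "")
  cat("  ages ", min(x$ages), "-", max(x$ages), ", years ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  if (!is.null(x$deviance))
    cat("  Poisson deviance ", format(x$deviance, digits = 6),
        " (", x$iterations, " iterations, ",
        if (isTRUE(x$converged)) "converged" else "NOT converged", ")\n",
        sep = "")
  if (!is.null(x$K)) cat("  principal components:", x$K, "\n")
  invisible(x)
}

#' @export
summary.mortality_fit <- function(object, ...) {
  res <- residuals(object)
  cat("Model:", object$model, "\n")
  print(object)
  if (is.matrix(res)) {
    cat("  in-sample RMSE of log rates:",
        format(sqrt(mean(res^2, na.rm = TRUE)), digits = 4), "\n")
  }
  invisible(object)
}

#' @export
coef.mortality_fit <- function(object, ...) {
  out <- object[intersect(c("alpha", "beta", "betas", "kappa", "kappas",
                            "gamma", "beta0", "xc", "mu", "components",
                            "scores"), names(object))]
  out[!vapply(out, is.null, TRUE)]
}

#' @export
fitted.mortality_fit <- function(object, ...) object$logm_fit

#' @export
residuals.mortality_fit <- function(object, ...) {
  if (!is.null(object$residuals)) return(object$residuals)
  obs <- if (!is.null(object$log_rates)) object$log_rates
  else log(log_safe_rates(derive_rates(object$deaths, object$exposures)))
  if (is.list(obs)) return(Map(function(o, f) o - f, obs, object$logm_fit))
  obs - object$logm_fit
}

#' @export
plot.mortality_fit <- function(x, ...) {
  kap <- if (!is.null(x$kappa)) rbind(x$kappa) else
    if (!is.null(x$kappas)) x$kappas else
      if (!is.null(x$scores) && ncol(x$scores)) t(x$scores) else NULL
  if (is.null(kap)) {
    graphics::plot.new()
    graphics::title(main = paste(x$model, "(no period index to plot)"))
    return(invisible(x))
  }
  graphics::matplot(x$years, t(kap), type = "l", lty = 1,
                    xlab = "year", ylab = "period index / score",
                    main = paste(x$model, "period indexes"), ...)
  invisible(x)
}
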