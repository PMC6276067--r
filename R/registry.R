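#' The model registry
#'
#' The 17 pool members, keyed by the conventional labels used throughout
#' the package (and by [run_pipeline()] configs): 1-8 the Poisson
#' age-period-cohort family, 9-12 the SVD Lee-Carter variants
#' distinguished by their period-index adjustment, 13-17 the functional
#' time-series variants.  Labels 15-17 model several populations
#' jointly and require a [population_set()].
#'
#' @return data.frame with columns `label`, `name`, `family`, `needs`,
#'   `description`.
#' @export
model_registry <- function() {
  data.frame(
    label = 1:17,
    name = c("LC_POIS", "RH", "APC", "CBD", "M6", "M7", "M8", "PLAT",
             "LC_TOTAL_DEATHS", "LC_DEATHS_DIST", "LC_E0", "LC_NONE",
             "FDM", "ROBUST_FDM", "PRODUCT_RATIO", "MULTIVARIATE",
             "MULTILEVEL"),
    family = c(rep("gapc", 8), rep("lc", 4), rep("fts", 5)),
    needs = c(rep("surface", 14), rep("popset", 3)),
    description = c(
      "Lee-Carter with Poisson error structure",
      "Renshaw-Haberman age-period-cohort",
      "Age-period-cohort",
      "Cairns-Blake-Dowd two-factor",
      "M6: CBD with cohort effect",
      "M7: quadratic CBD with cohort effect",
      "M8: CBD with age-modulated cohort effect",
      "Plat",
      "Lee-Carter (Gaussian), index refit to total deaths",
      "Lee-Carter (Gaussian), index refit to deaths distribution",
      "Lee-Carter (Gaussian), index refit to life expectancy",
      "Lee-Carter (Gaussian), no index adjustment",
      "Functional data model",
      "Robust functional data model",
      "Product-ratio coherent two-population model",
      "Multivariate (stacked) functional model",
      "Multilevel functional model"),
    stringsAsFactors = FALSE)
}

resolve_model <- function(model) {
  reg <- model_registry()
  if (is.numeric(model)) {
    ix <- match(as.integer(model), reg$label)
  } else {
    ix <- match(toupper(model), reg$name)
  }
  if (is.na(ix)) stop("unknown model '", model, "'", call. = FALSE)
  reg[ix, ]
}

#' Fit one model of the pool
#'
#' Single entry point over the three families.  `model` is a registry
#' label (1-17) or name (see [model_registry()]).  Single-population
#' models given a [population_set()] are fitted to every member and
#' returned as a named list of fits (class `mortality_fit_set`); joint
#' models (labels 15-17) require the population set.
#'
#' @param data a [mortality_surface()] or [population_set()].
#' @param model registry label or name.
#' @param K,K_common,K_specific numbers of principal components for the
#'   functional variants.
#' @param lambda,monotone smoothing controls for the functional variants.
#' @param ... passed to the family fitter (e.g. `tol`, `maxit`, `xc`).
#' @return A `mortality_fit` (or `mortality_fit_set`).
#' @examples
#' truth <- ground_truth()
#' s <- simulate_surface(truth, years = 1990:2010, seed = 7)
#' fit <- fit_mortality(s, "LC_POIS")
#' fit
#' @export
fit_mortality <- function(data, model, K = 6, K_common = 3, K_specific = 3,
                          lambda = NULL, monotone = TRUE, ...) {
  info <- resolve_model(model)
  if (info$needs == "popset" && !inherits(data, "population_set"))
    stop(info$name, " requires a population_set", call. = FALSE)
  if (info$needs == "surface" && inherits(data, "population_set")) {
    fits <- lapply(data, fit_mortality, model = model, K = K,
                   lambda = lambda, monotone = monotone, ...)
    return(structure(fits, class = "mortality_fit_set", model = info$name))
  }
  switch(info$name,
    LC_POIS = , RH = , APC = , CBD = , M6 = , M7 = , PLAT =
      fit_gapc(info$name, data, ...),
    M8 = {
      dots <- list(...)
      if (is.null(dots$xc)) estimate_xc(data, ...)$fit
      else fit_gapc("M8", data, ...)
    },
    LC_TOTAL_DEATHS = fit_lc_svd(data, adjustment = "total_deaths"),
    LC_DEATHS_DIST = fit_lc_svd(data, adjustment = "deaths_distribution"),
    LC_E0 = fit_lc_svd(data, adjustment = "e0"),
    LC_NONE = fit_lc_svd(data, adjustment = "none"),
    FDM = {
      sm <- smooth_log_rates(data, lambda = lambda, monotone = monotone)
      f <- fit_fpca(sm, K = K, variant = "FDM", ages = data$ages,
                    years = data$years)
      f$label <- data$label
      f
    },
    ROBUST_FDM = {
      f <- robust_refit(data, K = K, lambda = lambda, monotone = monotone, ...)
      f$label <- data$label
      f
    },
    PRODUCT_RATIO = fit_product_ratio(data, K = K, lambda = lambda,
                                      monotone = monotone),
    MULTIVARIATE = fit_multivariate(data, K = K, lambda = lambda,
                                    monotone = monotone),
    MULTILEVEL = fit_multilevel(data, K_common = K_common,
                                K_specific = K_specific, lambda = lambda,
                                monotone = monotone))
}

#' @export
forecast.mortality_fit_set <- function(object, h = 10, level = 0.8, ...) {
  out <- lapply(object, forecast, h = h, level = level, ...)
  structure(out, class = "mortality_forecast_set")
}

#' @export
print.mortality_fit_set <- function(x, ...) {
  cat("Fits of", attr(x, "model"), "for populations:",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
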