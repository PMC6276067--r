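#' Equal weights over the superior set
#'
#' Every model retained by the model confidence set receives weight
#' 1/(size of the superior set); eliminated models receive 0.
#'
#' @param mcs_result an `mcs_result` from [run_mcs()].
#' @return A `combination_weights` object (named weights summing to 1,
#'   `scheme = "EQUAL_MCS"`).
#' @export
equal_weights <- function(mcs_result) {
  sup <- mcs_result$superior
  if (!length(sup)) stop("empty superior set", call. = FALSE)
  all_models <- c(sup, mcs_result$eliminated$label)
  w <- stats::setNames(rep(0, length(all_models)), all_models)
  w[sup] <- 1 / length(sup)
  structure(list(weights = w, scheme = "EQUAL_MCS"),
            class = "combination_weights")
}

#' Inverse-validation-error weights over all models
#'
#' The baseline combiner: every model gets weight proportional to the
#' reciprocal of its mean validation loss, standardized to sum to 1, so
#' models that forecast better in validation weigh more but none is
#' excluded.
#'
#' @param validation_losses named vector of positive mean losses per
#'   model (or a loss matrix, whose column means are used).
#' @return A `combination_weights` object (`scheme = "INVERSE_ERROR"`).
#' @export
inverse_error_weights <- function(validation_losses) {
  if (is.matrix(validation_losses))
    validation_losses <- colMeans(validation_losses)
  if (any(validation_losses < 0))
    stop("negative mean loss", call. = FALSE)
  if (any(validation_losses == 0))
    stop("a model has zero validation loss; inverse-error weights are ",
         "undefined (the perfect model should simply be used)", call. = FALSE)
  w <- 1 / validation_losses
  w <- w / sum(w)
  structure(list(weights = w, scheme = "INVERSE_ERROR"),
            class = "combination_weights")
}

#' @export
print.combination_weights <- function(x, ...) {
  cat("Combination weights (", x$scheme, "):\n", sep = "")
  print(round(x$weights[x$weights > 0], 4))
  invisible(x)
}

#' Combine member forecasts
#'
#' Convex combination of the members' point forecasts and of their
#' interval bounds with the given weights.  All positively weighted
#' members must share ages, forecast years and interval level.  The
#' combined forecast lies elementwise in the convex hull of its members.
#'
#' @param results named list of `mortality_forecast` objects (names are
#'   model labels matching the weights).
#' @param weights a `combination_weights` object.
#' @return A `mortality_forecast` with the member labels and weights in
#'   `members`.
#' @export
combine_forecasts <- function(results, weights) {
  w <- weights$weights
  use <- names(w)[w > 0]
  miss <- setdiff(use, names(results))
  if (length(miss))
    stop("no forecast supplied for weighted model(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  members <- results[use]
  ref <- members[[1L]]
  for (f in members) {
    if (!identical(f$ages, ref$ages) || !identical(f$years, ref$years) ||
        !identical(f$level, ref$level))
      stop("member forecasts disagree on ages/years/level", call. = FALSE)
  }
  acc <- function(field) Reduce(`+`, Map(function(f, wi) wi * f[[field]],
                                         members, w[use]))
  out <- new_forecast(paste0("COMBINED[", weights$scheme, "]"), ref$label,
                      ref$ages, ref$years, acc("point"), acc("lower"),
                      acc("upper"), ref$level)
  out$members <- w[use]
  out
}
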