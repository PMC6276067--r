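#' Expanding-window evaluation plan
#'
#' Forecast origins run from `train_end` to `test_end - horizon`; models
#' are refitted at every origin on all data up to it and forecast
#' `horizon` steps ahead.  Forecast years in `(train_end,
#' validation_end]` form the validation set (used for model trimming),
#' years in `(validation_end, test_end]` the test set.
#'
#' @param train_end last year of the initial training window.
#' @param validation_end last validation year.
#' @param test_end last test year.
#' @param horizon steps ahead per origin (default 1).
#' @return A `split_plan` object.
#' @export
split_plan <- function(train_end, validation_end, test_end, horizon = 1) {
  stopifnot(train_end < validation_end, validation_end < test_end,
            horizon >= 1)
  structure(list(train_end = train_end, validation_end = validation_end,
                 test_end = test_end, horizon = horizon),
            class = "split_plan")
}

#' Run the expanding-window forecast exercise
#'
#' For each origin year from `plan$train_end` up to `plan$test_end -
#' plan$horizon`, every requested model is refitted on the data up to
#' the origin and forecast `horizon` steps ahead.  Failures are caught,
#' logged with a warning, and excluded downstream.
#'
#' @param data a [mortality_surface()] or [population_set()].
#' @param models registry labels (or names), see [model_registry()].
#' @param plan a [split_plan()].
#' @param level interval coverage \eqn{1-\alpha}.
#' @param n_paths,seed simulation controls for the Poisson family.
#' @param ... passed to [fit_mortality()].
#' @return An `expanding_window` object: `forecasts[[model]][[origin]]`
#'   is a named list population -> `mortality_forecast`; `failures` is a
#'   data.frame of (model, origin, message).
#' @export
expanding_window <- function(data, models, plan, level = 0.8,
                             n_paths = 1000, seed = 1, ...) {
  first_year <- if (inherits(data, "population_set")) data[[1L]]$years[1L]
  else data$years[1L]
  last_year <- if (inherits(data, "population_set")) max(data[[1L]]$years)
  else max(data$years)
  h <- plan$horizon
  if (plan$train_end < first_year + 2 || plan$test_end > last_year)
    stop("plan outside the data range", call. = FALSE)
  if (plan$train_end - first_year + 1 < 3)
    stop("need at least 3 training years", call. = FALSE)
  origins <- plan$train_end:(plan$test_end - h)
  labels <- vapply(models, function(m) resolve_model(m)$name, "")
  fc <- stats::setNames(vector("list", length(models)), labels)
  fails <- data.frame(model = character(0), origin = integer(0),
                      message = character(0))
  for (mi in seq_along(models)) {
    per_origin <- stats::setNames(vector("list", length(origins)),
                                  origins)
    for (oi in seq_along(origins)) {
      orig <- origins[oi]
      dat_o <- if (inherits(data, "population_set"))
        population_set(lapply(data, restrict_years, first_year, orig))
      else restrict_years(data, first_year, orig)
      res <- try({
        fit <- fit_mortality(dat_o, models[mi], ...)
        f <- forecast(fit, h = h, level = level, n_paths = n_paths,
                      seed = seed + 1000L * oi)
        normalize_forecast_set(f, data)
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        fails <- rbind(fails, data.frame(
          model = labels[mi], origin = orig,
          message = conditionMessage(attr(res, "condition"))))
      } else per_origin[[oi]] <- res
    }
    if (all(vapply(per_origin, is.null, TRUE)))
      warning("model ", labels[mi], " failed at every origin")
    fc[[mi]] <- per_origin
  }
  if (nrow(fails))
    warning(nrow(fails), " (model, origin) fits failed and are excluded")
  structure(list(plan = plan, level = level, origins = origins,
                 populations = if (inherits(data, "population_set"))
                   names(data) else data$label,
                 forecasts = fc, failures = fails, seed = seed),
            class = "expanding_window")
}

# every forecast becomes a named list population -> mortality_forecast
normalize_forecast_set <- function(f, data) {
  if (inherits(f, "mortality_forecast")) {
    nm <- if (inherits(data, "population_set")) f$label else data$label
    out <- stats::setNames(list(f), nm)
  } else out <- f
  out
}

#' Root mean squared forecast error of one forecast curve
#'
#' \eqn{\sqrt{(1/k)\sum_j (y_j - \hat y_j)^2}} across the ages of a
#' single forecast curve; computed on the log-rate scale throughout the
#' package.
#'
#' @param actual,forecast numeric vectors over the same ages.
#' @return The scalar loss.
#' @export
rmsfe <- function(actual, forecast) {
  if (length(actual) != length(forecast))
    stop("length mismatch between actual and forecast", call. = FALSE)
  sqrt(mean((actual - forecast)^2))
}

#' Interval score of a central prediction interval
#'
#' For nominal coverage \eqn{1-\alpha}, the pointwise score is the
#' interval width plus \eqn{2/\alpha} times any exceedance:
#' \deqn{S_\alpha = (u - l) + \frac{2}{\alpha}(l - y)\,1\{y < l\} +
#'       \frac{2}{\alpha}(y - u)\,1\{y > u\}.}
#' Smaller is better; the score is minimized by narrow intervals that
#' cover.
#'
#' @param lower,upper interval bounds per age (`lower <= upper`).
#' @param actual realized values per age.
#' @param alpha significance level (default 0.2 for 80\% intervals).
#' @return List with per-age `scores` and their `mean` over the curve.
#' @export
interval_score <- function(lower, upper, actual, alpha = 0.2) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (any(lower > upper))
    stop("lower bound exceeds upper bound", call. = FALSE)
  s <- (upper - lower) +
    (2 / alpha) * (lower - actual) * (actual < lower) +
    (2 / alpha) * (actual - upper) * (actual > upper)
  list(scores = s, mean = mean(s))
}

#' Build the loss matrix of an expanding-window run
#'
#' One row per evaluation year, one column per model; each entry is the
#' per-curve loss (RMSFE of log rates, or the mean interval score) of
#' that model's forecast for that year, for one population.  Rows with a
#' failed fit for any model are dropped (pairwise exclusion happens by
#' keeping only years where all requested models succeeded, so the
#' matrix entries are comparable).
#'
#' @param ew an [expanding_window()] result.
#' @param actual the full [mortality_surface()] or [population_set()]
#'   holding the realized rates.
#' @param loss_type `"rmsfe"` or `"mis"`.
#' @param population population label (defaults to the first).
#' @param subset `"validation"`, `"test"` or `"all"`.
#' @param alpha significance level for the interval score.
#' @return Matrix with evaluation years as rownames and model names as
#'   colnames; class `loss_matrix`.
#' @export
build_loss_matrix <- function(ew, actual, loss_type = c("rmsfe", "mis"),
                              population = NULL,
                              subset = c("validation", "test", "all"),
                              alpha = NULL) {
  loss_type <- match.arg(loss_type)
  subset <- match.arg(subset)
  if (is.null(alpha)) alpha <- 1 - ew$level
  pop <- if (is.null(population)) ew$populations[1L] else population
  act_surface <- if (inherits(actual, "population_set")) actual[[pop]] else actual
  act_lr <- log(log_safe_rates(act_surface))
  h <- ew$plan$horizon
  eval_years <- ew$origins + h
  keep <- switch(subset,
    validation = eval_years > ew$plan$train_end &
      eval_years <= ew$plan$validation_end,
    test = eval_years > ew$plan$validation_end,
    all = rep(TRUE, length(eval_years)))
  eval_years <- eval_years[keep]
  origins <- ew$origins[keep]
  models <- names(ew$forecasts)
  L <- matrix(NA_real_, length(eval_years), length(models),
              dimnames = list(eval_years, models))
  for (mi in seq_along(models)) {
    for (oi in seq_along(origins)) {
      f <- ew$forecasts[[mi]][[as.character(origins[oi])]]
      if (is.null(f) || is.null(f[[pop]])) next
      fc <- f[[pop]]
      hix <- match(eval_years[oi], fc$years)
      if (is.na(hix)) next
      yact <- act_lr[, as.character(eval_years[oi])]
      L[oi, mi] <- if (loss_type == "rmsfe")
        rmsfe(yact, fc$point[, hix])
      else interval_score(fc$lower[, hix], fc$upper[, hix], yact, alpha)$mean
    }
  }
  ok <- stats::complete.cases(L)
  if (!all(ok))
    warning(sum(!ok), " evaluation year(s) dropped (failed fits)")
  L <- L[ok, , drop = FALSE]
  if (nrow(L) < 1L) stop("no usable evaluation years", call. = FALSE)
  structure(L, class = c("loss_matrix", class(L)), loss_type = loss_type)
}
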