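#' Default pipeline configuration
#'
#' @param ... overrides of the default fields.
#' @return A config list understood by [run_pipeline()].
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    data = NULL,                      # path to a long CSV; NULL = synthetic
    synthetic = list(n_pops = 2, cross_corr = 0.8, years = c(1975, 2015),
                     seed = 1),
    models = c(1, 4, 8, 9, 13, 15),
    plan = list(train_end = 1995, validation_end = 2005, test_end = 2015,
                horizon = 1),
    loss_types = c("rmsfe", "mis"),
    statistics = c("Tmax", "TR"),
    alpha_test = 0.10,
    alpha_interval = 0.2,
    B = 500,
    n_paths = 1000,
    seed = 1,
    output_dir = NULL)
  up <- list(...)
  cfg[names(up)] <- up
  cfg
}

load_pipeline_data <- function(cfg) {
  if (!is.null(cfg$data)) return(read_mortality_csv(cfg$data))
  sy <- cfg$synthetic
  yrs <- if (length(sy$years) == 2L) sy$years[1]:sy$years[2] else sy$years
  truth <- ground_truth()
  if (is.null(sy$n_pops) || sy$n_pops < 2)
    simulate_surface(truth, years = yrs, seed = sy$seed %||% cfg$seed)
  else
    simulate_population_set(truth, n_pops = sy$n_pops,
                            cross_corr = sy$cross_corr %||% 0.8,
                            years = yrs, seed = sy$seed %||% cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full trimming-and-combination pipeline
#'
#' End-to-end reproduction of the experiment design: expanding-window
#' refits of every pool model over validation and test years; validation
#' loss matrices (RMSFE and/or mean interval score) per population;
#' model confidence set trimming of the pool at the configured test
#' level per loss type and statistic; equal-weight combination over each
#' superior set and inverse-validation-error combination over the whole
#' pool; test-period loss tables for every model and combiner.  All
#' randomness is seeded from the config, so a rerun is bit-identical.
#'
#' @param config a config list from [pipeline_config()], or the path of
#'   a YAML file with the same fields.
#' @return A `pipeline_result`: `data`, the [expanding_window()] object,
#'   and per population the validation/test loss matrices, `mcs_result`s
#'   (by loss type and statistic), combination weights, and the
#'   test-loss summary table.  When `config$output_dir` is set, CSV and
#'   JSON artifacts plus a run log are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- do.call(pipeline_config,
                                              yaml::read_yaml(config))
  cfg <- config
  reg <- model_registry()
  bad <- setdiff(vapply(cfg$models, function(m) resolve_model(m)$name, ""),
                 reg$name)
  if (length(bad)) stop("unknown models: ", paste(bad, collapse = ", "))
  data <- load_pipeline_data(cfg)
  plan <- split_plan(cfg$plan$train_end, cfg$plan$validation_end,
                     cfg$plan$test_end, cfg$plan$horizon %||% 1)
  level <- 1 - cfg$alpha_interval
  ew <- expanding_window(data, cfg$models, plan, level = level,
                         n_paths = cfg$n_paths, seed = cfg$seed)
  pops <- ew$populations
  per_pop <- stats::setNames(vector("list", length(pops)), pops)
  for (p in pops) {
    val <- list(); tst <- list(); mcs <- list(); wts <- list()
    comb_loss <- list()
    for (lt in cfg$loss_types) {
      val[[lt]] <- build_loss_matrix(ew, data, lt, population = p,
                                     subset = "validation",
                                     alpha = cfg$alpha_interval)
      tst[[lt]] <- build_loss_matrix(ew, data, lt, population = p,
                                     subset = "test",
                                     alpha = cfg$alpha_interval)
      mcs[[lt]] <- list(); wts[[lt]] <- list()
      for (st in cfg$statistics) {
        mc <- run_mcs(val[[lt]], alpha = cfg$alpha_test, statistic = st,
                      B = cfg$B, seed = cfg$seed)
        mcs[[lt]][[st]] <- mc
        wts[[lt]][[st]] <- equal_weights(mc)
      }
      wts[[lt]][["INVERSE_ERROR"]] <- inverse_error_weights(val[[lt]])
      comb_loss[[lt]] <- combined_test_losses(ew, data, p, lt,
                                              wts[[lt]],
                                              alpha = cfg$alpha_interval)
    }
    summary_tab <- lapply(cfg$loss_types, function(lt)
      c(colMeans(tst[[lt]]), colMeans(comb_loss[[lt]])))
    names(summary_tab) <- cfg$loss_types
    per_pop[[p]] <- list(validation_losses = val, test_losses = tst,
                         combined_test_losses = comb_loss,
                         mcs = mcs, weights = wts,
                         mean_test_loss = summary_tab)
  }
  out <- structure(list(config = cfg, data = data, expanding = ew,
                        populations = per_pop),
                   class = "pipeline_result")
  if (!is.null(cfg$output_dir)) write_pipeline_artifacts(out)
  out
}

combined_test_losses <- function(ew, data, pop, loss_type, weight_sets,
                                 alpha) {
  plan <- ew$plan
  act <- if (inherits(data, "population_set")) data[[pop]] else data
  act_lr <- log(log_safe_rates(act))
  h <- plan$horizon
  origins <- ew$origins[ew$origins + h > plan$validation_end]
  L <- matrix(NA_real_, length(origins), length(weight_sets),
              dimnames = list(origins + h, names(weight_sets)))
  for (oi in seq_along(origins)) {
    o <- as.character(origins[oi])
    members <- lapply(ew$forecasts, function(fm) fm[[o]][[pop]])
    if (any(vapply(members, is.null, TRUE))) next
    yr <- origins[oi] + h
    for (wi in seq_along(weight_sets)) {
      cf <- combine_forecasts(members, weight_sets[[wi]])
      hix <- match(yr, cf$years)
      yact <- act_lr[, as.character(yr)]
      L[oi, wi] <- if (loss_type == "rmsfe")
        rmsfe(yact, cf$point[, hix])
      else interval_score(cf$lower[, hix], cf$upper[, hix], yact, alpha)$mean
    }
  }
  L[stats::complete.cases(L), , drop = FALSE]
}

write_pipeline_artifacts <- function(res) {
  dir <- res$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in names(res$populations)) {
    pp <- res$populations[[p]]
    for (lt in names(pp$validation_losses)) {
      utils::write.csv(pp$validation_losses[[lt]],
                       file.path(dir, paste0("losses_validation_", p, "_",
                                             lt, ".csv")))
      utils::write.csv(pp$test_losses[[lt]],
                       file.path(dir, paste0("losses_test_", p, "_", lt,
                                             ".csv")))
      utils::write.csv(pp$combined_test_losses[[lt]],
                       file.path(dir, paste0("losses_test_combined_", p,
                                             "_", lt, ".csv")))
      for (st in names(pp$mcs[[lt]]))
        write_mcs_json(pp$mcs[[lt]][[st]],
                       file.path(dir, paste0("mcs_", p, "_", lt, "_", st,
                                             ".json")))
    }
  }
  log <- res$config
  log$output_dir <- NULL
  yaml::write_yaml(log, file.path(dir, "run_log.yaml"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", length(x$config$models), "models, populations:",
      paste(names(x$populations), collapse = ", "), "\n")
  for (p in names(x$populations)) {
    cat("\n== ", p, " ==\n", sep = "")
    for (lt in names(x$populations[[p]]$mean_test_loss)) {
      cat("mean test ", lt, " (x100):\n", sep = "")
      print(round(100 * x$populations[[p]]$mean_test_loss[[lt]], 3))
    }
  }
  invisible(x)
}

#' Write a synthetic fixture as a long CSV
#'
#' @param path output path.
#' @param n_pops number of populations (1 for a single surface).
#' @param years year range.
#' @param seed integer seed.
#' @param ... passed to [ground_truth()].
#' @return The path, invisibly.
#' @export
simulate_fixture_csv <- function(path, n_pops = 2, years = 1975:2015,
                                 seed = 1, ...) {
  truth <- ground_truth(...)
  obj <- if (n_pops >= 2)
    simulate_population_set(truth, n_pops = n_pops, years = years,
                            seed = seed)
  else simulate_surface(truth, years = years, seed = seed)
  write_mortality_csv(obj, path)
}
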