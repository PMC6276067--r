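#' Loss differentials and their bootstrap variances
#'
#' From an N-by-m loss matrix, computes the pairwise mean loss
#' differentials \eqn{\bar d_{\rho\xi}} (antisymmetric), the row means
#' \eqn{\bar d_{\rho\cdot} = (1/m)\sum_\xi \bar d_{\rho\xi}}, and
#' moving-block bootstrap estimates of the variances of both, using a
#' circular block bootstrap of the time index shared by all model
#' columns.  When `block_length` is not given it is chosen by
#' [select_block_length()].
#'
#' @param losses N-by-m numeric matrix (rows = evaluation points,
#'   columns = models).
#' @param B bootstrap replicates.
#' @param block_length positive integer block length, or `NULL` to select.
#' @param seed integer seed.
#' @return A `differential_set` with `dbar_pair`, `dbar_dot`,
#'   `var_pair`, `var_dot`, the bootstrap column means `boot_means`
#'   (B-by-m), `block_length`, `B`, `seed`.
#' @export
compute_differentials <- function(losses, B = 5000, block_length = NULL,
                                  seed = 1) {
  L <- as.matrix(losses)
  N <- nrow(L); m <- ncol(L)
  if (m < 2L) stop("need at least 2 models", call. = FALSE)
  if (N < 2L) stop("need at least 2 evaluation points", call. = FALSE)
  if (any(!is.finite(L))) stop("losses must be finite", call. = FALSE)
  if (is.null(colnames(L))) colnames(L) <- paste0("model", seq_len(m))
  lbar <- colMeans(L)
  dbar_pair <- outer(lbar, lbar, `-`)
  dbar_dot <- rowMeans(dbar_pair)
  if (is.null(block_length)) {
    if (N < 5L) block_length <- 1L
    else {
      pairs <- utils::combn(m, 2)
      D <- apply(pairs, 2, function(p) L[, p[1]] - L[, p[2]])
      block_length <- select_block_length(D)
    }
  }
  set.seed(seed)
  nb <- ceiling(N / block_length)
  boot_means <- matrix(0, B, m, dimnames = list(NULL, colnames(L)))
  for (b in seq_len(B)) {
    starts <- sample.int(N, nb, replace = TRUE)
    idx <- as.vector(outer(seq_len(block_length) - 1L, starts, `+`))
    idx <- ((idx - 1L) %% N) + 1L       # circular wrap
    idx <- idx[seq_len(N)]
    boot_means[b, ] <- colMeans(L[idx, , drop = FALSE])
  }
  ctr <- sweep(boot_means, 2, lbar)     # deviations from sample means
  var_pair <- matrix(0, m, m, dimnames = dimnames(dbar_pair))
  for (r in seq_len(m)) for (s in seq_len(m)) if (r != s)
    var_pair[r, s] <- mean((ctr[, r] - ctr[, s])^2)
  dot_dev <- ctr - rowMeans(ctr)
  var_dot <- colMeans(dot_dev^2)
  structure(list(models = colnames(L), N = N, m = m,
                 dbar_pair = dbar_pair, dbar_dot = dbar_dot,
                 var_pair = var_pair, var_dot = var_dot,
                 boot_means = boot_means, lbar = lbar,
                 block_length = block_length, B = B, seed = seed),
            class = "differential_set")
}

#' Bootstrap block length from the loss differentials
#'
#' For every pairwise differential series, an autoregressive model is
#' fitted with the order chosen by AIC (up to
#' \eqn{p_{max} = \lfloor N^{1/3}\rfloor + 1}) and refitted by least
#' squares; the number of significant AR coefficients is counted, at a
#' Bonferroni-corrected two-sided 5\% level across the \eqn{p_{max}}
#' candidate lags (so spurious dependence is rarely found).  A
#' significant lag-\eqn{\ell} dependence needs resampling blocks that
#' span \eqn{\ell + 1} points to survive, so the block length is one
#' plus the maximum significant-coefficient count over all pairs:
#' independent differentials give length 1, autocorrelated ones length
#' 2 or more.  Degenerate (constant) series contribute 0.
#'
#' @param differentials N-by-(number of pairs) matrix of loss
#'   differential series.
#' @return A positive integer block length.
#' @export
select_block_length <- function(differentials) {
  D <- as.matrix(differentials)
  N <- nrow(D)
  if (N < 5L) stop("need at least 5 evaluation points", call. = FALSE)
  pmax_ord <- floor(N^(1 / 3)) + 1L
  crit <- stats::qnorm(1 - 0.025 / pmax_ord)
  nsig <- apply(D, 2, function(x) {
    if (stats::sd(x) < 1e-12) return(0L)
    ar_fit <- try(stats::ar(x, aic = TRUE, order.max = pmax_ord,
                            method = "yule-walker"), silent = TRUE)
    if (inherits(ar_fit, "try-error")) return(0L)
    p <- ar_fit$order
    if (p == 0L) return(0L)
    emb <- stats::embed(x, p + 1L)
    fit <- stats::lm.fit(cbind(1, emb[, -1, drop = FALSE]), emb[, 1])
    dfres <- length(fit$residuals) - (p + 1L)
    if (dfres <= 0) return(p)           # saturated: count all as significant
    s2 <- sum(fit$residuals^2) / dfres
    XtX <- crossprod(cbind(1, emb[, -1, drop = FALSE]))
    se <- sqrt(diag(s2 * chol2inv(chol(XtX))))[-1]
    sum(abs(fit$coefficients[-1] / se) > crit)
  })
  max(1L, 1L + max(nsig))
}

#' Equal-predictive-ability test on a model set
#'
#' Computes the studentized statistics \eqn{t_{\rho\xi} = \bar
#' d_{\rho\xi}/\sqrt{\widehat{Var}(\bar d_{\rho\xi})}} and
#' \eqn{t_{\rho\cdot}}, the range statistic \eqn{T_R =
#' \max|t_{\rho\xi}|} or the semi-quadratic \eqn{T_{max} = \max
#' t_{\rho\cdot}}, and a bootstrap p-value from the same block-bootstrap
#' replicates with the differentials recentered at their sample means.
#' The worst model is identified by the elimination rule matching the
#' statistic (both in standardized form).
#'
#' @param diff a `differential_set` from [compute_differentials()].
#' @param statistic `"Tmax"` or `"TR"`.
#' @return List with `statistic`, `observed`, `p_value`, `worst` (model
#'   label), and the matrices/vectors `t_pair`, `t_dot`.
#' @export
test_epa <- function(diff, statistic = c("Tmax", "TR")) {
  statistic <- match.arg(statistic)
  m <- diff$m
  safe_div <- function(num, den) {
    t <- num / sqrt(den)
    t[!is.finite(t) & abs(num) < 1e-14] <- 0
    if (any(!is.finite(t))) {
      warning("zero bootstrap variance with nonzero mean differential; ",
              "p-value forced to 0")
      t[!is.finite(t)] <- sign(num[!is.finite(t)]) * Inf
    }
    t
  }
  t_pair <- safe_div(diff$dbar_pair, diff$var_pair)
  diag(t_pair) <- 0
  t_dot <- safe_div(diff$dbar_dot, diff$var_dot)
  ctr <- sweep(diff$boot_means, 2, diff$lbar)
  if (statistic == "TR") {
    observed <- max(abs(t_pair))
    boot_stat <- apply(ctr, 1, function(u) {
      tp <- outer(u, u, `-`) / sqrt(diff$var_pair)
      tp[!is.finite(tp)] <- 0
      max(abs(tp))
    })
    worst <- diff$models[which.max(apply(t_pair, 1, max))]
  } else {
    observed <- max(t_dot)
    boot_stat <- apply(ctr, 1, function(u) {
      td <- (u - mean(u)) / sqrt(diff$var_dot)
      td[!is.finite(td)] <- 0
      max(td)
    })
    worst <- diff$models[which.max(t_dot)]
  }
  p <- mean(boot_stat >= observed)
  if (!is.finite(observed)) p <- 0
  if (observed == 0 && all(abs(diff$dbar_pair) < 1e-14)) p <- 1
  list(statistic = statistic, observed = observed, p_value = p,
       worst = worst, t_pair = t_pair, t_dot = t_dot)
}

#' The model confidence set procedure
#'
#' Sequential elimination: test equal predictive ability on the current
#' set; if the bootstrap p-value is at least `alpha`, stop and declare
#' the survivors the superior set; otherwise eliminate the worst model
#' (by the rule matching the chosen statistic), record the step p-value
#' and the MCS p-value (the running maximum of step p-values), and
#' repeat on the survivors with freshly computed differentials.
#' Bootstrap replicates are redrawn each round with a deterministically
#' advanced seed, so a run is exactly reproducible.
#'
#' @param losses N-by-m loss matrix (a `loss_matrix` or plain matrix with
#'   model column names).
#' @param alpha test level; 0.10 gives the 90\% confidence set.
#' @param statistic `"Tmax"` or `"TR"`.
#' @param B bootstrap replicates per round.
#' @param block_length block length; `NULL` selects it from the data
#'   once, on the full model set.
#' @param seed integer seed.
#' @return An `mcs_result`: `superior` labels, `eliminated` data.frame
#'   (label, step_p, mcs_p, in elimination order), `p_final`, settings.
#' @export
run_mcs <- function(losses, alpha = 0.10, statistic = c("Tmax", "TR"),
                    B = 5000, block_length = NULL, seed = 1) {
  statistic <- match.arg(statistic)
  L <- as.matrix(losses)
  if (is.null(colnames(L))) colnames(L) <- paste0("model", seq_len(ncol(L)))
  models <- colnames(L)
  if (ncol(L) == 1L)
    return(structure(list(superior = models, eliminated = data.frame(
      label = character(0), step_p = numeric(0), mcs_p = numeric(0)),
      p_final = 1, statistic = statistic, alpha = alpha, B = B,
      block_length = block_length, seed = seed), class = "mcs_result"))
  if (is.null(block_length)) {
    if (nrow(L) < 5L) block_length <- 1L
    else {
      pairs <- utils::combn(ncol(L), 2)
      D <- apply(pairs, 2, function(p) L[, p[1]] - L[, p[2]])
      block_length <- select_block_length(D)
    }
  }
  surviving <- models
  elim <- data.frame(label = character(0), step_p = numeric(0),
                     mcs_p = numeric(0))
  round <- 0L
  p_running <- 0
  p_final <- 1
  repeat {
    round <- round + 1L
    if (length(surviving) == 1L) { p_final <- 1; break }
    dset <- compute_differentials(L[, surviving, drop = FALSE], B = B,
                                  block_length = block_length,
                                  seed = seed + round)
    tst <- test_epa(dset, statistic)
    if (tst$p_value >= alpha) { p_final <- tst$p_value; break }
    p_running <- max(p_running, tst$p_value)
    elim <- rbind(elim, data.frame(label = tst$worst, step_p = tst$p_value,
                                   mcs_p = p_running))
    surviving <- setdiff(surviving, tst$worst)
  }
  structure(list(superior = surviving, eliminated = elim,
                 p_final = max(p_final, p_running),
                 statistic = statistic, alpha = alpha, B = B,
                 block_length = block_length, seed = seed),
            class = "mcs_result")
}

#' @export
print.mcs_result <- function(x, ...) {
  cat("Model confidence set (", x$statistic, ", level ",
      100 * (1 - x$alpha), "%)\n", sep = "")
  cat("  superior set: ", paste(x$superior, collapse = ", "), "\n", sep = "")
  if (nrow(x$eliminated)) {
    cat("  eliminated (in order):\n")
    print(x$eliminated, row.names = FALSE)
  } else cat("  no model eliminated\n")
  invisible(x)
}

#' JSON serialization of an MCS result
#'
#' @param x an `mcs_result`.
#' @param path file path; `NULL` returns the JSON string.
#' @return The path (invisibly) or the JSON string.
#' @export
write_mcs_json <- function(x, path = NULL) {
  obj <- list(superior = x$superior,
              eliminated = x$eliminated,
              p_final = x$p_final,
              statistic = x$statistic, alpha = x$alpha, B = x$B,
              block_length = x$block_length, seed = x$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
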