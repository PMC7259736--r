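#' MacKenzie-Bailey chi-square discrepancy
#'
#' The detection-history chi-square: within each stratum (year-stage by
#' default) the observed counts of the 8 possible three-count histories
#' are compared with their expected counts under the model,
#' `E_c = sum_i P(h_c | psi_i, p_i)` over the stratum's units (the
#' marginal [unit_likelihood()]).  Cells with expected count below
#' `pool_threshold` are pooled into a single remainder cell per stratum —
#' the standard small-expected-frequency correction; a pooled cell whose
#' expected count is still zero is dropped with a warning.
#'
#' @param y n x 3 binary history matrix.
#' @param psi Per-unit occupancy probabilities, length n.
#' @param p Per-unit detection probabilities (constant across the three
#'   counts), length n.
#' @param strata Factor/vector of stratum labels, length n (default: one
#'   stratum).
#' @param pool_threshold Minimum expected count for a cell to stand alone.
#' @return The chi-square discrepancy `sum (O - E)^2 / E`.
#' @export
mb_statistic <- function(y, psi, p, strata = NULL, pool_threshold = 2) {
  y <- as.matrix(y)
  n <- nrow(y)
  stopifnot(ncol(y) == 3, all(y %in% c(0, 1)),
            length(psi) == n, length(p) == n,
            all(psi >= 0 & psi <= 1), all(p >= 0 & p <= 1))
  if (is.null(strata)) strata <- rep(1L, n)
  stopifnot(length(strata) == n)
  cell <- as.integer(y %*% c(4, 2, 1)) + 1L
  probs <- .cell_probs(psi, p)
  total <- 0
  for (st in unique(strata)) {
    idx <- strata == st
    E <- colSums(probs[idx, , drop = FALSE])
    O <- tabulate(cell[idx], nbins = 8)
    small <- E < pool_threshold
    if (sum(!small)) {
      total <- total + sum((O[!small] - E[!small])^2 / E[!small])
    }
    if (any(small)) {
      Ep <- sum(E[small]); Op <- sum(O[small])
      if (Ep > 0) {
        total <- total + (Op - Ep)^2 / Ep
      } else if (Op > 0) {
        warning("stratum ", st, ": pooled cell has zero expected count; ",
                "dropped from the statistic")
      }
    }
  }
  total
}

#' Bayesian MacKenzie-Bailey posterior-predictive goodness-of-fit
#'
#' For a subsample of posterior draws, computes the observed-data
#' discrepancy `T_obs` ([mb_statistic()] at that draw's per-unit `psi` and
#' `p`), simulates a replicate dataset from the fitted model's generative
#' form (`z ~ Bernoulli(psi)`, three Bernoulli(`z p`) counts) and computes
#' the replicate discrepancy `T_rep`.  Fit is judged from the 95% credible
#' interval of `D = T_rep - T_obs`: the model is "adequate" when the
#' interval includes 0.  The Bayesian p-value `P(T_rep >= T_obs)` is also
#' reported.
#'
#' @param fit An `occu_fit`.
#' @param n_draws Number of posterior draws to use (subsampled evenly
#'   across the stored draws; at least 100 are required).
#' @param pool_threshold Passed to [mb_statistic()].
#' @return Object of class `gof_report`: list with per-draw `t_obs`,
#'   `t_rep`, `d`, the 95% `bci` of `d`, `p_value`, and `adequate`.
#' @export
posterior_predictive_gof <- function(fit, n_draws = 500, pool_threshold = 2) {
  stopifnot(inherits(fit, "occu_fit"))
  linpred <- .make_linpred(fit)
  pars <- posterior_matrix(fit)
  total <- nrow(pars)
  if (total < 100) stop("too few posterior draws for a GOF check (< 100)")
  n_draws <- min(n_draws, total)
  use <- unique(round(seq(1, total, length.out = n_draws)))
  n <- fit$data$n
  y <- fit$data$y
  strata <- paste(fit$data$year, fit$data$stage, sep = ":")
  t_obs <- t_rep <- numeric(length(use))
  for (d in seq_along(use)) {
    pp <- linpred(use[d])
    t_obs[d] <- mb_statistic(y, pp$psi, pp$p, strata, pool_threshold)
    z_rep <- rbinom(n, 1, pp$psi)
    y_rep <- matrix(rbinom(3 * n, 1, rep(z_rep * pp$p, 3)), ncol = 3)
    t_rep[d] <- mb_statistic(y_rep, pp$psi, pp$p, strata, pool_threshold)
  }
  if (sd(t_obs) == 0 && sd(t_rep) == 0) {
    stop("degenerate draws: discrepancy has zero variance")
  }
  dd <- t_rep - t_obs
  bci <- unname(quantile(dd, c(0.025, 0.975)))
  structure(list(
    t_obs = t_obs, t_rep = t_rep, d = dd,
    bci = bci,
    p_value = mean(t_rep >= t_obs),
    adequate = bci[1] <= 0 && bci[2] >= 0,
    n_draws = length(use)
  ), class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat("Bayesian MacKenzie-Bailey goodness-of-fit (", x$n_draws,
      " draws)\n", sep = "")
  cat(sprintf("  95%% BCI of T_rep - T_obs: %.2f to %.2f\n",
              x$bci[1], x$bci[2]))
  cat(sprintf("  Bayesian p-value P(T_rep >= T_obs): %.3f\n", x$p_value))
  cat("  verdict:", if (x$adequate) "adequate fit (BCI includes 0)"
      else "inadequate fit (BCI excludes 0)", "\n")
  invisible(x)
}
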