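#' Stack posterior draws across chains
#'
#' @param fit An `occu_fit`.
#' @return Numeric matrix of draws (rows) by parameters (columns), with a
#'   `chain` attribute giving the chain id of each row; the per-stage model
#'   indicator and inclusion-indicator draws, when present, are attached as
#'   attributes `model` and `incl`.
#' @export
posterior_matrix <- function(fit) {
  stopifnot(inherits(fit, "occu_fit"))
  pars <- do.call(rbind, lapply(fit$chains, `[[`, "params"))
  attr(pars, "chain") <- rep(seq_along(fit$chains),
                             vapply(fit$chains, function(ch) nrow(ch$params), 0L))
  if (!is.null(fit$chains[[1]]$model)) {
    attr(pars, "model") <- do.call(rbind, lapply(fit$chains, `[[`, "model"))
  }
  if (!is.null(fit$chains[[1]]$incl)) {
    attr(pars, "incl") <- do.call(rbind, lapply(fit$chains, `[[`, "incl"))
  }
  pars
}

# build a closure mapping one posterior draw to per-unit (psi, p); used by
# goodness-of-fit and prediction code.  Indices into the draw vector are
# resolved once.
.make_linpred <- function(fit) {
  meta <- fit$meta
  flags <- meta$flags
  pars <- posterior_matrix(fit)
  cn <- colnames(pars)
  n <- meta$n; J <- meta$J; S <- meta$S
  X <- meta$X
  stage_i <- meta$stage_i; year_i <- meta$year_i
  site_i <- meta$site_i; cell_i <- meta$cell_i
  i_alpha <- match(paste0("alpha[", meta$stages, "]"), cn)
  ua_idx <- which(meta$ua, arr.ind = TRUE)
  i_beta <- if (J > 0 && nrow(ua_idx)) {
    match(paste0("beta[", colnames(X)[ua_idx[, 1]], ",",
                 meta$stages[ua_idx[, 2]], "]"), cn)
  } else integer(0)
  i_mu_p <- match("mu_p", cn)
  i_eps <- if (flags$det_re) match(paste0("eps[", meta$cells, "]"), cn)
  i_u <- if (flags$site_re) match(paste0("u[", meta$sites, "]"), cn)
  i_eta <- if (flags$obs_re) match(paste0("eta[", seq_len(n), "]"), cn)
  i_delta <- if (flags$beta_by_year && nrow(ua_idx)) {
    vapply(seq_len(nrow(ua_idx)), function(r) {
      match(paste0("delta[", colnames(X)[ua_idx[r, 1]], ",",
                   meta$stages[ua_idx[r, 2]], ",", meta$years, "]"), cn)
    }, integer(length(meta$years)))
  }
  model_draws <- attr(pars, "model")
  incl_draws <- attr(pars, "incl")
  col_group <- NULL
  if (meta$mode == "screen") {
    col_group <- integer(J)
    for (g in seq_along(meta$groups)) col_group[meta$groups[[g]]] <- g
  }

  function(d) {
    row <- pars[d, ]
    lpsi <- row[i_alpha][stage_i]
    if (flags$site_re) lpsi <- lpsi + row[i_u][site_i]
    if (length(i_beta)) {
      # activity of each union-active coefficient under this draw's model
      act <- rep(TRUE, nrow(ua_idx))
      if (meta$mode == "models") {
        act <- vapply(seq_len(nrow(ua_idx)), function(r) {
          s <- ua_idx[r, 2]
          meta$incl_list[[s]][model_draws[d, s], ua_idx[r, 1]]
        }, TRUE)
      } else if (meta$mode == "screen") {
        act <- incl_draws[d, col_group[ua_idx[, 1]]] == 1L
      }
      for (r in which(act)) {
        j <- ua_idx[r, 1]; s <- ua_idx[r, 2]
        on <- stage_i == s
        b <- row[i_beta[r]]
        if (flags$beta_by_year) {
          b <- b + row[i_delta[, r]][year_i]
          lpsi[on] <- lpsi[on] + X[on, j] * b[on]
        } else {
          lpsi[on] <- lpsi[on] + X[on, j] * b
        }
      }
    }
    lp <- rep(row[i_mu_p], n)
    if (flags$det_re) lp <- lp + row[i_eps][cell_i]
    if (flags$obs_re) lp <- lp + row[i_eta]
    list(psi = plogis(lpsi), p = plogis(lp))
  }
}

#' @export
print.occu_fit <- function(x, ...) {
  st <- x$settings
  cat("occu_fit:", st$n_chains, "chains x", st$n_iter, "iterations (burn-in",
      paste0(st$n_burnin, ","), "thin", paste0(st$thin, ")\n"))
  cat("  units:", x$data$n, " mode:", x$meta$mode, "\n")
  fl <- x$meta$flags
  cat("  random effects: site =", fl$site_re, " year-stage detection =",
      fl$det_re, " observation =", fl$obs_re, "\n")
  invisible(x)
}

#' Posterior summaries of model parameters
#'
#' @param object An `occu_fit`.
#' @param probs Quantiles to report.
#' @param ... Unused.
#' @return Data frame with one row per parameter: posterior mean, SD and
#'   the requested quantiles over all chains.
#' @export
summary.occu_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  pars <- posterior_matrix(object)
  out <- data.frame(
    parameter = colnames(pars),
    mean = colMeans(pars),
    sd = apply(pars, 2, sd),
    row.names = NULL
  )
  q <- t(apply(pars, 2, quantile, probs = probs))
  colnames(q) <- paste0("q", probs * 100)
  cbind(out, q)
}
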