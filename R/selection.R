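#' Screen covariates by posterior inclusion probability
#'
#' Phase-one covariate screening: fits the global model with independent
#' Kuo-Mallick inclusion indicators (each term enters the linear predictor
#' as `I_j * beta_j * x_j` with a Bernoulli(0.5) prior on `I_j`;
#' zero-inflated pairs are tied) and retains the covariates whose marginal
#' posterior inclusion probability exceeds 0.5 — the median-probability-
#' model rule.  A covariate at exactly 0.5 is excluded (the rule drops
#' `P(I_j = 1 | y) <= 0.5`).
#'
#' @param data An [occu_data()] with the global design matrix.
#' @param priors,settings Passed to [occu_mcmc()].
#' @param ... Further arguments to [occu_mcmc()] (random-effect flags).
#' @return List with `inclusion` (data frame: term group, posterior
#'   inclusion probability, retained flag), `retained` (character vector
#'   of retained design columns), `fit` (the underlying `occu_fit`), and
#'   `switch_rate` (mean per-iteration indicator switch rate, a mixing
#'   monitor).
#' @export
screen_covariates <- function(data, priors = occu_priors(),
                              settings = mcmc_settings(), ...) {
  fit <- occu_mcmc(data, screen = TRUE, priors = priors,
                   settings = settings, ...)
  incl <- do.call(rbind, lapply(fit$chains, `[[`, "incl"))
  pip <- colMeans(incl)
  switch_rate <- mean(vapply(fit$chains, function(ch) {
    m <- ch$incl
    if (nrow(m) < 2) return(0)
    mean(abs(diff(m)) > 0)
  }, 0))
  groups <- fit$meta$groups
  retained_groups <- names(pip)[pip > 0.5]
  retained_cols <- unlist(lapply(which(pip > 0.5), function(g) {
    colnames(data$X)[groups[[g]]]
  }))
  list(
    inclusion = data.frame(group = names(pip), inclusion_prob = unname(pip),
                           retained = unname(pip > 0.5), row.names = NULL),
    retained = as.character(retained_cols),
    switch_rate = switch_rate,
    fit = fit
  )
}

#' Summarize cross-product model selection
#'
#' Turns the latent model-indicator draws of a selection fit into
#' stage-specific posterior model probabilities (indicator frequencies),
#' per-covariate posterior inclusion probabilities (the summed probability
#' of the models containing the covariate), and conditional — i.e.
#' model-averaged — coefficient estimates computed only over the draws in
#' which the covariate is included.
#'
#' @param fit An `occu_fit` produced with `model_sets`.
#' @return Object of class `selection_summary`: list with, per stage,
#'   `model_probs` (named vector summing to 1), `inclusion` (named vector
#'   per covariate), and `conditional` (data frame: term, conditional
#'   posterior mean, 2.5% and 97.5% quantiles, inclusion probability;
#'   covariates never sampled into the model get `NA` summaries).
#' @export
summarize_selection <- function(fit) {
  stopifnot(inherits(fit, "occu_fit"))
  if (fit$meta$mode != "models") {
    stop("fit was not run with candidate model sets")
  }
  pars <- posterior_matrix(fit)
  model_draws <- attr(pars, "model")
  meta <- fit$meta
  out <- list()
  for (s in seq_len(meta$S)) {
    st <- meta$stages[s]
    inc <- meta$incl_list[[s]]
    M <- nrow(inc)
    freq <- tabulate(model_draws[, s], nbins = M)
    probs <- setNames(freq / sum(freq), meta$model_names[[s]])
    terms <- colnames(meta$X)[meta$ua[, s]]
    inclusion <- vapply(terms, function(tr) {
      sum(probs[inc[, tr]])
    }, 0)
    cond <- do.call(rbind, lapply(terms, function(tr) {
      col <- paste0("beta[", tr, ",", st, "]")
      in_draw <- inc[model_draws[, s], tr]
      b <- pars[in_draw, col]
      if (!length(b)) {
        data.frame(term = tr, mean = NA_real_, lower = NA_real_,
                   upper = NA_real_, inclusion_prob = inclusion[[tr]])
      } else {
        data.frame(term = tr, mean = mean(b),
                   lower = unname(quantile(b, 0.025)),
                   upper = unname(quantile(b, 0.975)),
                   inclusion_prob = inclusion[[tr]])
      }
    }))
    if (is.null(cond)) {
      cond <- data.frame(term = character(), mean = numeric(),
                         lower = numeric(), upper = numeric(),
                         inclusion_prob = numeric())
    }
    out[[st]] <- list(model_probs = probs, inclusion = inclusion,
                      conditional = cond)
  }
  structure(out, class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  for (st in names(x)) {
    cat(st, "model probabilities:\n")
    print(round(x[[st]]$model_probs, 3))
  }
  invisible(x)
}

#' Export a selection summary as a stage-by-model probability table
#'
#' @param sel A `selection_summary`.
#' @return Data frame, stages as rows and model names as columns; models
#'   not considered in a stage are `NA`.
#' @export
model_prob_table <- function(sel) {
  stopifnot(inherits(sel, "selection_summary"))
  all_models <- unique(unlist(lapply(sel, function(s) names(s$model_probs))))
  out <- do.call(rbind, lapply(names(sel), function(st) {
    p <- sel[[st]]$model_probs
    row <- setNames(rep(NA_real_, length(all_models)), all_models)
    row[names(p)] <- p
    as.data.frame(as.list(row), check.names = FALSE)
  }))
  rownames(out) <- names(sel)
  out
}
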