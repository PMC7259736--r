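# shared builders for small in-code fixtures

make_survey_df <- function(site = "A", year = 2011, date = "2011-08-20",
                           counts = c(0, 0, 0), radius = "infinite",
                           stage = "fall_harvest") {
  data.frame(site_id = site, year = year, date = as.Date(date),
             stage = stage, count1 = counts[1], count2 = counts[2],
             count3 = counts[3], radius_class = radius,
             stringsAsFactors = FALSE)
}

# homogeneous intercept-only scenario used by several MCMC tests
flat_scenario <- function(n_sites, psi, p, seed, beta = list(),
                          stage = "fall_harvest") {
  al <- setNames(qlogis(psi), stage)
  sim_scenario(n_sites = n_sites, years = 2011, stages = stage,
               mu_p = qlogis(p), sigma_p = 0, sigma_obs = 0, sigma_site = 0,
               alpha = al, beta = beta, seed = seed)
}

# exact grid posterior for the homogeneous 2-parameter model
# (independent oracle for the sampler: marginal likelihood on a grid of
# logit-scale intercepts with the same N(0, 10^2) priors)
grid_posterior_psi_p <- function(y, prior_sd = 10, lim = 4, step = 0.02) {
  k <- rowSums(y)
  nk <- tabulate(k + 1, nbins = 4) # counts of units with 0..3 detections
  a <- seq(-lim, lim, by = step)
  m <- seq(-lim, lim, by = step)
  psi <- plogis(a); p <- plogis(m)
  lp <- outer(seq_along(a), seq_along(m), Vectorize(function(i, j) {
    lk <- vapply(0:3, function(kk) {
      log(psi[i] * p[j]^kk * (1 - p[j])^(3 - kk) +
            (1 - psi[i]) * (kk == 0))
    }, 0)
    sum(nk * lk) + dnorm(a[i], 0, prior_sd, log = TRUE) +
      dnorm(m[j], 0, prior_sd, log = TRUE)
  }))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(mean_psi = sum(rowSums(w) * psi),
       mean_p = sum(colSums(w) * p),
       mode = c(a = a[which(rowSums(w) == max(rowSums(w)))[1]],
                m = m[which(colSums(w) == max(colSums(w)))[1]]))
}

# minimal hand-built occu_fit for summary/prediction oracles
fake_fit <- function(params, stages, X, model = NULL, incl_list = NULL,
                     model_names = NULL, ua = NULL) {
  J <- ncol(X)
  if (is.null(ua)) ua <- matrix(TRUE, J, length(stages),
                                dimnames = list(colnames(X), stages))
  meta <- list(mode = if (is.null(model)) "fixed" else "models",
               S = length(stages), stages = stages, X = X, J = J,
               ua = ua, incl_list = incl_list, model_names = model_names,
               flags = list(site_re = FALSE, det_re = FALSE,
                            obs_re = FALSE, beta_by_year = FALSE))
  structure(list(
    chains = list(list(params = params, model = model, incl = NULL)),
    meta = meta,
    data = list(n = 0),
    settings = mcmc_settings(n_chains = 1)
  ), class = "occu_fit")
}
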