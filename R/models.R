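#' Define a candidate occurrence model
#'
#' A candidate model is an inclusion pattern: the set of design-matrix
#' columns entering the occurrence linear predictor (every model contains
#' the stage intercept).  Zero-inflated covariate pairs must be included
#' or excluded together, and any interaction term requires both of its
#' main effects.
#'
#' @param name Model label (e.g. `"M2"`).
#' @param terms Character vector of design-matrix column names (may be
#'   empty for the intercept-only model).
#' @param interactions Optional named list mapping an interaction term to
#'   the character vector of its main-effect terms, used for validation.
#' @return Object of class `occu_model`.
#' @export
candidate_model <- function(name, terms = character(), interactions = list()) {
  stopifnot(is.character(name), length(name) == 1, is.character(terms))
  for (int in names(interactions)) {
    if (int %in% terms && !all(interactions[[int]] %in% terms)) {
      stop("interaction '", int, "' requires its main effects in the model")
    }
  }
  structure(list(name = name, terms = unique(terms)), class = "occu_model")
}

#' Final per-stage candidate model sets
#'
#' The six-model candidate set used in the final analysis, restricted per
#' stage to the biologically plausible subset: M1 intercept-only; M2 cone
#' pair (presence/absence + density); M3 landscape area of whitebark pine;
#' M4 landscape area of Douglas-fir; M5 cone pair + whitebark area; M6
#' whitebark area + Douglas-fir area.  Cone models are only available in
#' late summer and fall harvest (cones are not on the trees otherwise);
#' Douglas-fir area only in breeding and post-harvest; early summer
#' considers only M1 and M3.
#'
#' @param cone_pair Column-name pair of the zero-inflated cone covariate
#'   (absence indicator first).
#' @param wbp_area,df_area Column names of the landscape-area covariates.
#' @param stages Stages to return sets for (default all five).
#' @return Named list (per stage) of lists of [candidate_model()]s.
#' @export
final_candidate_sets <- function(cone_pair = c("cone_density_absent",
                                               "cone_density"),
                                 wbp_area = "wbp_area",
                                 df_area = "df_area",
                                 stages = stage_levels()) {
  stopifnot(length(cone_pair) == 2)
  m1 <- candidate_model("M1")
  m2 <- candidate_model("M2", cone_pair)
  m3 <- candidate_model("M3", wbp_area)
  m4 <- candidate_model("M4", df_area)
  m5 <- candidate_model("M5", c(cone_pair, wbp_area))
  m6 <- candidate_model("M6", c(wbp_area, df_area))
  avail <- list(
    breeding     = list(m1, m3, m4, m6),
    early_summer = list(m1, m3),
    late_summer  = list(m1, m2, m3, m5),
    fall_harvest = list(m1, m2, m3, m5),
    post_harvest = list(m1, m3, m4, m6)
  )
  stopifnot(all(stages %in% names(avail)))
  avail[stages]
}

#' Prior specification for the occupancy model
#'
#' Diffuse priors on all hyperparameters: Normal(0, `beta_sd`^2) on
#' logit-scale intercepts, coefficient hyper-means and the detection
#' hyper-mean; Uniform(0, `sd_upper`) on every standard deviation;
#' Bernoulli(`inclusion_prior`) on Kuo-Mallick covariate-inclusion
#' indicators; uniform over each stage's candidate models.
#'
#' @param beta_sd Prior SD of location parameters (logit scale).
#' @param sd_upper Upper bound of the uniform priors on SDs.
#' @param inclusion_prior Prior inclusion probability of each covariate in
#'   the screening phase.
#' @return Object of class `occu_priors`.
#' @export
occu_priors <- function(beta_sd = 10, sd_upper = 10, inclusion_prior = 0.5) {
  stopifnot(beta_sd > 0, sd_upper > 0,
            inclusion_prior > 0, inclusion_prior < 1)
  structure(list(beta_sd = beta_sd, sd_upper = sd_upper,
                 inclusion_prior = inclusion_prior), class = "occu_priors")
}

#' MCMC settings
#'
#' Chain configuration for [occu_mcmc()].  The default is the desk-scale
#' configuration (3 chains of 4,000 iterations, 1,000 burn-in, thin 1)
#' adequate for the moderately sized posteriors in this package's
#' simulations; `paper_scale = TRUE` switches to the full-scale
#' configuration used for the field analysis (3 x 60,000 iterations,
#' 20,000 burn-in, thin 1).
#'
#' @param n_chains Number of chains.
#' @param n_iter Iterations per chain (including burn-in).
#' @param n_burnin Burn-in iterations discarded per chain; random-walk
#'   proposal scales adapt during burn-in only.
#' @param thin Thinning interval.
#' @param seed Integer seed; fixed seed gives bitwise-reproducible chains.
#' @param paper_scale Use the full-scale configuration.
#' @return Object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, n_iter = 4000, n_burnin = 1000,
                          thin = 1, seed = 1L, paper_scale = FALSE) {
  if (paper_scale) {
    n_iter <- 60000; n_burnin <- 20000; thin <- 1
  }
  stopifnot(n_chains >= 1, n_iter > n_burnin, n_burnin >= 0, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "mcmc_settings")
}
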