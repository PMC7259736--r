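#' Define a simulation scenario for the survey design
#'
#' A scenario bundles every quantity the generator needs to emulate the
#' study's survey design: the site x year x stage layout (three ten-minute
#' counts per survey unit), hierarchical detection structure (logit-scale
#' hyper-mean with year-stage and observation-level random effects),
#' stage-specific occurrence intercepts with a site random effect and
#' covariate effects, and zero-inflated, right-skewed habitat covariates.
#' Defaults reproduce the study conditions: 238 sites over 2009-2013 and
#' five annual-cycle stages, detection hyper-mean at logit 0.5 with
#' year-stage spread, strongly zero-inflated cone and importance-value
#' covariates with lognormal positive parts, and landscape areas on the
#' scales reported for the southern Greater Yellowstone Ecosystem.
#'
#' @param n_sites Number of survey sites.
#' @param years Integer vector of survey years.
#' @param stages Character vector of annual-cycle stages surveyed.
#' @param mu_p Detection hyper-mean on the logit scale.
#' @param sigma_p SD of year-stage detection random effects (logit scale).
#' @param sigma_obs SD of the observation-level (survey-unit) detection
#'   random effect.
#' @param alpha Named vector of stage-specific occurrence intercepts
#'   (logit scale); names must cover `stages`.
#' @param sigma_site SD of the site random effect on occurrence.
#' @param beta Named list per stage: named numeric vector of occurrence
#'   coefficients on design-matrix columns (standardized scale).  Stages
#'   absent from the list get no covariate effects.
#' @param sigma_beta_year SD of year-level deviations around each
#'   stage-level coefficient (0 = coefficients constant across years).
#' @param cone_pi0,cone_meanlog,cone_sdlog Zero-inflation probability and
#'   lognormal parameters of cone density (cones/ha), drawn per site-year.
#' @param wbp_iv_pi0,wbp_iv_meanlog,wbp_iv_sdlog Same for whitebark pine
#'   importance value (capped at 300).
#' @param df_iv_pi0,df_iv_meanlog,df_iv_sdlog Same for Douglas-fir
#'   importance value (capped at 300).
#' @param wbp_area_mean,wbp_area_sd Normal parameters of the area (ha) of
#'   whitebark pine within 32.6 km (truncated strictly positive).
#' @param df_area_meanlog,df_area_sdlog Lognormal parameters of the area
#'   (ha) of Douglas-fir within 3.2 km.
#' @param tree_density_meanlog,tree_density_sdlog Lognormal parameters of
#'   tree density (trees/ha).
#' @param seed Integer seed; a fixed seed makes the generator fully
#'   reproducible.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_sites = 238,
                         years = 2009:2013,
                         stages = stage_levels(),
                         mu_p = 0,
                         sigma_p = 0.7,
                         sigma_obs = 0.3,
                         alpha = c(breeding = -0.9, early_summer = -1.0,
                                   late_summer = 2.7, fall_harvest = 4.2,
                                   post_harvest = 2.1),
                         sigma_site = 0.75,
                         beta = list(),
                         sigma_beta_year = 0,
                         cone_pi0 = 0.65, cone_meanlog = log(500),
                         cone_sdlog = 1.1,
                         wbp_iv_pi0 = 0.49, wbp_iv_meanlog = log(80),
                         wbp_iv_sdlog = 0.8,
                         df_iv_pi0 = 0.66, df_iv_meanlog = log(100),
                         df_iv_sdlog = 0.9,
                         wbp_area_mean = 45000, wbp_area_sd = 20000,
                         df_area_meanlog = log(228), df_area_sdlog = 0.9,
                         tree_density_meanlog = log(800),
                         tree_density_sdlog = 0.5,
                         seed = 1L) {
  stopifnot(n_sites >= 1, length(years) >= 1,
            all(stages %in% stage_levels()),
            sigma_p >= 0, sigma_obs >= 0, sigma_site >= 0,
            sigma_beta_year >= 0,
            cone_pi0 >= 0, cone_pi0 <= 1, wbp_iv_pi0 >= 0, wbp_iv_pi0 <= 1,
            df_iv_pi0 >= 0, df_iv_pi0 <= 1,
            all(stages %in% names(alpha)),
            is.list(beta))
  if (length(beta)) stopifnot(all(names(beta) %in% stages))
  structure(as.list(environment()), class = "sim_scenario")
}

#' Generate site covariates for a scenario
#'
#' Draws the habitat covariate tables the analysis consumes: static
#' per-site covariates (importance values, landscape areas, tree density)
#' and a per-site-per-year cone density table.  Cone density and the two
#' importance values are zero-inflated with lognormal positive parts
#' (right-skewed, mean well above the median, as in the field data);
#' landscape areas are strictly positive.  Fully reproducible under the
#' scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @return List with `sites` (data frame keyed by `site_id`) and `cones`
#'   (data frame keyed by `site_id` and `year` with `cone_density`).
#' @export
generate_covariates <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  s <- scenario
  set.seed(s$seed)
  n <- s$n_sites
  rzi <- function(n, pi0, meanlog, sdlog, cap = Inf) {
    x <- ifelse(runif(n) < pi0, 0, pmin(rlnorm(n, meanlog, sdlog), cap))
    x
  }
  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(n)),
    wbp_importance = rzi(n, s$wbp_iv_pi0, s$wbp_iv_meanlog, s$wbp_iv_sdlog, 300),
    df_importance = rzi(n, s$df_iv_pi0, s$df_iv_meanlog, s$df_iv_sdlog, 300),
    wbp_area = pmax(rnorm(n, s$wbp_area_mean, s$wbp_area_sd), 500),
    df_area = rlnorm(n, s$df_area_meanlog, s$df_area_sdlog),
    tree_density = rlnorm(n, s$tree_density_meanlog, s$tree_density_sdlog)
  )
  grid <- expand.grid(site_id = sites$site_id, year = as.integer(s$years),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cones <- data.frame(
    grid,
    cone_density = rzi(nrow(grid), s$cone_pi0, s$cone_meanlog, s$cone_sdlog)
  )
  list(sites = sites, cones = cones)
}

#' Generate detection histories under known truth
#'
#' Simulates the full generative model on the scenario's site x year x
#' stage layout: latent occupancy `z ~ Bernoulli(psi)` with
#' `logit(psi) = alpha_s + u_site + sum(beta * x)` over the stage's active
#' covariates, detection `logit(p) = mu_p + eps_{year,stage} + eta_unit`,
#' and three conditionally independent Bernoulli counts per unit given
#' `z * p`.  The returned truth record stores every latent quantity, so
#' each unit's `psi` and `p` can be recomputed exactly.
#'
#' @param scenario A [sim_scenario()]; its `beta` field names the active
#'   covariates and effects per stage (the "true model").
#' @param covariates Covariate tables from [generate_covariates()];
#'   regenerated from the scenario if omitted.
#' @param radius_class Radius class to label the records with.
#' @return Object of class `occu_sim`: list with `records` (survey-record
#'   data frame, one row per unit with `count1..count3`), `X` (standardized
#'   design matrix over units), `truth` (latent values and parameters) and
#'   `scenario`.
#' @export
generate_detections <- function(scenario, covariates = NULL,
                                radius_class = "infinite") {
  stopifnot(inherits(scenario, "sim_scenario"),
            radius_class %in% radius_levels())
  s <- scenario
  if (is.null(covariates)) covariates <- generate_covariates(s)
  set.seed(s$seed + 1L)

  units <- expand.grid(site_id = covariates$sites$site_id,
                       year = as.integer(s$years),
                       stage = s$stages,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(units)
  si <- match(units$site_id, covariates$sites$site_id)
  ci <- match(paste(units$site_id, units$year),
              paste(covariates$cones$site_id, covariates$cones$year))
  covs <- data.frame(
    cone_density = covariates$cones$cone_density[ci],
    wbp_importance = covariates$sites$wbp_importance[si],
    df_importance = covariates$sites$df_importance[si],
    wbp_area = covariates$sites$wbp_area[si],
    df_area = covariates$sites$df_area[si],
    tree_density = covariates$sites$tree_density[si]
  )
  zi_vars <- c("cone_density", "wbp_importance", "df_importance")
  zi_use <- zi_vars[vapply(zi_vars, function(v) any(covs[[v]] > 0), TRUE)]
  cont <- c("wbp_area", "df_area", "tree_density")
  cont_use <- cont[vapply(cont, function(v) sd(covs[[v]]) > 0, TRUE)]
  X <- build_design(covs, continuous = cont_use, zero_inflated = zi_use)

  # latent structure
  u <- rnorm(s$n_sites, 0, s$sigma_site)
  cells <- unique(units[, c("year", "stage")])
  eps <- rnorm(nrow(cells), 0, s$sigma_p)
  cell_id <- match(paste(units$year, units$stage),
                   paste(cells$year, cells$stage))
  eta <- rnorm(n, 0, s$sigma_obs)

  # stage-year effective coefficients around the stage-level effect
  beta_eff <- array(0, dim = c(ncol(X), length(s$stages), length(s$years)),
                    dimnames = list(colnames(X), s$stages,
                                    as.character(s$years)))
  for (st in names(s$beta)) {
    b <- s$beta[[st]]
    stopifnot(all(names(b) %in% colnames(X)))
    for (j in names(b)) {
      beta_eff[j, st, ] <- b[[j]] +
        rnorm(length(s$years), 0, s$sigma_beta_year)
    }
  }
  yi <- match(as.character(units$year), as.character(s$years))
  sti <- match(units$stage, s$stages)
  xb <- numeric(n)
  if (ncol(X) > 0) {
    for (j in seq_len(ncol(X))) {
      xb <- xb + X[, j] * beta_eff[cbind(j, sti, yi)]
    }
  }
  lpsi <- unname(s$alpha[units$stage]) + u[si] + xb
  psi <- plogis(lpsi)
  z <- rbinom(n, 1, psi)
  lp <- s$mu_p + eps[cell_id] + eta
  p <- plogis(lp)
  counts <- matrix(rbinom(3 * n, 1, rep(z * p, each = 3)), ncol = 3,
                   byrow = TRUE)

  windows <- stage_windows(s$years)
  wi <- match(paste(units$year, units$stage),
              paste(windows$year, windows$stage))
  mid <- windows$start[wi] + floor((windows$end[wi] - windows$start[wi]) / 2)

  records <- data.frame(
    site_id = units$site_id, year = units$year, date = mid,
    stage = units$stage,
    count1 = counts[, 1], count2 = counts[, 2], count3 = counts[, 3],
    radius_class = radius_class
  )
  structure(list(
    records = records, X = X,
    truth = list(z = z, psi = psi, p = p, u = u,
                 eps = eps, cells = cells, eta = eta,
                 alpha = s$alpha[s$stages], beta_eff = beta_eff,
                 units = units, site_index = si, cell_index = cell_id),
    covariates = covariates, scenario = s
  ), class = "occu_sim")
}

#' Write a simulated dataset to plain-text files
#'
#' Exports the survey records and covariate tables in the CSV dialects the
#' ingest functions read, plus the truth record as a JSON sidecar.
#'
#' @param sim An `occu_sim` from [generate_detections()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "occu_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    surveys = file.path(dir, "surveys.csv"),
    sites = file.path(dir, "site_covariates.csv"),
    cones = file.path(dir, "cone_density.csv"),
    truth = file.path(dir, "truth.json")
  )
  write.csv(sim$records, paths["surveys"], row.names = FALSE)
  write.csv(sim$covariates$sites, paths["sites"], row.names = FALSE)
  write.csv(sim$covariates$cones, paths["cones"], row.names = FALSE)
  tr <- sim$truth
  tr$cells <- NULL; tr$units <- NULL
  tr$beta_eff <- as.vector(tr$beta_eff)
  jsonlite::write_json(tr, paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
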