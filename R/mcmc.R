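# Metropolis-within-Gibbs sampler for the hierarchical occupancy model.
#
# The latent occupancy state z is sampled explicitly (data augmentation):
# given z, the occurrence part is a Bernoulli regression on the logit scale
# and the detection part a binomial regression over the three counts of the
# occupied units, which keeps every full conditional cheap — in particular
# the categorical full conditional of the latent model indicator.  The
# marginalized unit likelihood (unit_likelihood) is retained for oracle
# checks and goodness-of-fit.

# Bernoulli loglik on the logit scale: z*l + log(1 - plogis(l))
.ll_occ <- function(l, z) z * l + plogis(l, lower.tail = FALSE, log.p = TRUE)
# binomial(3) loglik of k detections on the logit scale
.ll_det <- function(l, k) k * l + 3 * plogis(l, lower.tail = FALSE, log.p = TRUE)

#' Fit the hierarchical occupancy model by MCMC
#'
#' Draws from the joint posterior of the single-season occupancy model with
#' imperfect detection.  Occurrence: `logit(psi_i) = alpha_s + u_site +
#' sum_j a_j beta_{j,s} x_ij`, where `a_j` is governed either by a fixed
#' inclusion pattern, by per-covariate Kuo-Mallick indicators
#' (`screen = TRUE`), or by a latent per-stage model indicator over
#' `model_sets` (cross-product model selection).  Detection:
#' `logit(p_i) = mu_p + eps_{year,stage} + eta_i` with the year-stage
#' effects drawn from a single hyper-distribution and an optional
#' observation-level effect per survey unit.  Coefficients of covariates
#' excluded under the current model evolve under their prior (pseudoprior),
#' preserving the correct joint posterior while keeping indicator moves
#' available.  Random-walk proposal scales adapt during burn-in only and
#' are frozen afterwards, preserving detailed balance of the retained
#' draws.  A fixed seed gives bitwise-reproducible chains.
#'
#' @param data An [occu_data()] object.
#' @param model_sets Named list (per stage present in `data`) of candidate
#'   model lists from [candidate_model()]; enables cross-product model
#'   selection.  `NULL` fits the fixed full model.
#' @param screen Use Kuo-Mallick inclusion indicators on every design
#'   column (zero-inflated pairs tied) instead of candidate sets.
#' @param priors An [occu_priors()] object.
#' @param settings An [mcmc_settings()] object.
#' @param site_re Include a site random effect on occurrence; default: only
#'   when some site contributes more than one unit.
#' @param det_re Include year-stage detection random effects; default: only
#'   when the data span more than one year-stage cell.
#' @param obs_re Include the observation-level detection random effect.
#' @param beta_by_year Let coefficients vary by year around their
#'   stage-level hyper-mean with a common SD.
#' @param store_z Also store the latent occupancy draws (n columns per
#'   draw); the per-unit posterior occupancy mean is always returned.
#' @return Object of class `occu_fit`: per-chain draw matrices with named
#'   columns, indicator draws, acceptance rates and metadata.
#' @export
occu_mcmc <- function(data, model_sets = NULL, screen = FALSE,
                      priors = occu_priors(), settings = mcmc_settings(),
                      site_re = NULL, det_re = NULL, obs_re = FALSE,
                      beta_by_year = FALSE, store_z = FALSE) {
  stopifnot(inherits(data, "occu_data"), inherits(priors, "occu_priors"),
            inherits(settings, "mcmc_settings"))
  if (data$n == 0) stop("empty data")
  if (screen && !is.null(model_sets)) {
    stop("choose either screening or candidate-set selection, not both")
  }
  prep <- .mcmc_prep(data, model_sets, screen)
  if (is.null(site_re)) site_re <- any(tabulate(as.integer(data$site)) > 1)
  if (is.null(det_re)) det_re <- prep$C > 1
  prep$flags <- list(site_re = isTRUE(site_re), det_re = isTRUE(det_re),
                     obs_re = isTRUE(obs_re),
                     beta_by_year = isTRUE(beta_by_year))
  chains <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    seed <- (settings$seed + 104729L * ch) %% .Machine$integer.max
    chains[[ch]] <- .occu_chain(prep, priors, settings, seed, store_z)
  }
  structure(list(chains = chains, data = data, meta = prep,
                 priors = priors, settings = settings,
                 model_sets = model_sets, screen = screen),
            class = "occu_fit")
}

# shared precomputation for all chains
.mcmc_prep <- function(data, model_sets, screen) {
  n <- data$n
  y <- data$y
  k <- rowSums(y)
  stage_i <- as.integer(data$stage)
  S <- nlevels(data$stage)
  stages <- levels(data$stage)
  year_i <- as.integer(data$year)
  years <- levels(data$year)
  Y <- length(years)
  site_i <- as.integer(data$site)
  nsite <- nlevels(data$site)
  cell_key <- paste(data$year, data$stage, sep = ":")
  cells <- unique(cell_key)
  cell_i <- match(cell_key, cells)
  C <- length(cells)
  X <- data$X
  J <- ncol(X)
  stage_units <- lapply(seq_len(S), function(s) which(stage_i == s))

  mode <- if (screen) "screen" else if (!is.null(model_sets)) "models"
          else "fixed"
  ua <- matrix(J > 0, J, S, dimnames = list(colnames(X), stages))
  incl_list <- NULL
  model_names <- NULL
  groups <- NULL
  if (mode == "models") {
    if (!setequal(names(model_sets), stages)) {
      stop("model_sets must name exactly the stages present in the data: ",
           paste(stages, collapse = ", "))
    }
    zi <- attr(X, "zi_pairs")
    incl_list <- vector("list", S)
    model_names <- vector("list", S)
    for (s in seq_len(S)) {
      ms <- model_sets[[stages[s]]]
      stopifnot(length(ms) >= 1,
                all(vapply(ms, inherits, TRUE, "occu_model")))
      inc <- matrix(FALSE, length(ms), max(J, 0),
                    dimnames = list(NULL, colnames(X)))
      for (m in seq_along(ms)) {
        tr <- ms[[m]]$terms
        if (!all(tr %in% colnames(X))) {
          stop("model '", ms[[m]]$name, "' uses unknown terms: ",
               paste(setdiff(tr, colnames(X)), collapse = ", "))
        }
        for (pr in zi) {
          if (xor(pr[1] %in% tr, pr[2] %in% tr)) {
            stop("model '", ms[[m]]$name, "' must include the zero-inflated ",
                 "pair (", paste(pr, collapse = ", "), ") together or not at all")
          }
        }
        inc[m, tr] <- TRUE
      }
      incl_list[[s]] <- inc
      model_names[[s]] <- vapply(ms, function(m) m$name, "")
      ua[, s] <- colSums(inc) > 0
    }
  } else if (mode == "screen") {
    if (J == 0) stop("screening requires at least one covariate")
    zi <- attr(X, "zi_pairs")
    grouped <- unlist(lapply(zi, function(pr) pr[pr %in% colnames(X)]))
    groups <- lapply(zi, function(pr) match(pr, colnames(X)))
    groups <- Filter(function(g) !anyNA(g), groups)
    singles <- setdiff(seq_len(J), unlist(groups))
    groups <- c(groups, as.list(singles))
    names(groups) <- vapply(groups, function(g) {
      paste(colnames(X)[g], collapse = "+")
    }, "")
  }

  list(n = n, y = y, k = k, det = k > 0,
       stage_i = stage_i, S = S, stages = stages,
       year_i = year_i, years = years, Y = Y,
       site_i = site_i, nsite = nsite, sites = levels(data$site),
       cell_i = cell_i, cells = cells, C = C,
       X = X, J = J, stage_units = stage_units,
       mode = mode, ua = ua, incl_list = incl_list,
       model_names = model_names, groups = groups)
}

# one chain; returns named draw matrices
.occu_chain <- function(prep, priors, settings, seed, store_z) {
  flags <- prep$flags
  site_re <- flags$site_re; det_re <- flags$det_re
  obs_re <- flags$obs_re; beta_by_year <- flags$beta_by_year
  set.seed(seed)
  n <- prep$n; k <- prep$k; det <- prep$det
  S <- prep$S; J <- prep$J; C <- prep$C
  X <- prep$X
  stage_i <- prep$stage_i; year_i <- prep$year_i
  site_i <- prep$site_i; cell_i <- prep$cell_i
  su <- prep$stage_units
  ua <- prep$ua
  mode <- prep$mode
  bsd <- priors$beta_sd; sd_up <- priors$sd_upper
  n_iter <- settings$n_iter; n_burn <- settings$n_burnin
  thin <- settings$thin
  n_save <- (n_iter - n_burn) %/% thin

  # --- initial state ---
  z <- pmax(det, rbinom(n, 1, 0.5))
  alpha <- vapply(seq_len(S), function(s) {
    qlogis(min(max(mean(det[su[[s]]]), 0.1), 0.9))
  }, 0)
  B <- matrix(0, max(J, 1), S)               # stage-level coefficients
  D <- if (beta_by_year) array(0, c(max(J, 1), S, prep$Y)) else NULL
  sigma_beta <- 0.5
  u <- numeric(prep$nsite); sigma_site <- 0.5
  mu_p <- qlogis(min(max(sum(k[det]) / max(3 * sum(det), 1), 0.1), 0.9))
  eps <- numeric(C); sigma_p <- 0.5
  eta <- numeric(n); sigma_obs <- 0.5
  m_cur <- integer(S)
  if (mode == "models") {
    for (s in seq_len(S)) m_cur[s] <- sample.int(nrow(prep$incl_list[[s]]), 1)
  }
  G <- if (mode == "screen") length(prep$groups) else 0L
  I_cur <- rep(1L, G)
  col_group <- integer(J)
  if (mode == "screen") {
    for (g in seq_len(G)) col_group[prep$groups[[g]]] <- g
  }

  active <- function() {
    # J x S logical matrix of currently active coefficients
    if (J == 0) return(matrix(FALSE, 0, S))
    switch(mode,
      fixed = ua,
      models = {
        a <- matrix(FALSE, J, S)
        for (s in seq_len(S)) a[, s] <- prep$incl_list[[s]][m_cur[s], ]
        a
      },
      screen = ua & matrix(I_cur[col_group] == 1L, J, S))
  }

  coef_js <- function(j, idx) {
    # effective coefficient of column j for the units in idx
    if (beta_by_year) B[j, stage_i[idx]] + D[cbind(j, stage_i[idx], year_i[idx])]
    else B[j, stage_i[idx]]
  }

  calc_lpsi <- function() {
    a <- active()
    lp <- alpha[stage_i] + if (site_re) u[site_i] else 0
    for (j in seq_len(J)) {
      on <- a[j, stage_i]
      if (any(on)) lp <- lp + X[, j] * coef_js(j, seq_len(n)) * on
    }
    lp
  }
  lpsi <- calc_lpsi()
  lp_det <- rep(mu_p, n) + (if (det_re) eps[cell_i] else 0) +
    (if (obs_re) eta else 0)

  # --- proposal scales (adapted during burn-in only) ---
  sc <- list(alpha = rep(0.5, S), beta = matrix(0.5, max(J, 1), S),
             delta = matrix(0.5, max(J, 1), S),
             u = rep(0.5, prep$nsite), eps = rep(0.5, C), eta = 0.5,
             mu_p = 0.3, lsig = rep(0.3, 4))  # site, p, obs, beta sds
  acc <- list(alpha = rep(0, S), beta = matrix(0, max(J, 1), S),
              delta = matrix(0, max(J, 1), S),
              u = rep(0, prep$nsite), eps = rep(0, C),
              eta = 0, eta_n = 0, mu_p = 0, lsig = rep(0, 4))
  att <- acc
  batch <- 50L

  mh <- function(cur, scale, dll_fun, lprior_fun) {
    # generic scalar MH step; returns c(new_value, accepted)
    prop <- cur + scale * rnorm(1)
    lr <- dll_fun(prop) + lprior_fun(prop) - lprior_fun(cur)
    if (is.finite(lr) && log(runif(1)) < lr) c(prop, 1) else c(cur, 0)
  }
  lp_norm <- function(x) dnorm(x, 0, bsd, log = TRUE)

  mh_lsig <- function(sig, scale, x) {
    ls <- log(sig)
    lsp <- ls + scale * rnorm(1)
    sp <- exp(lsp)
    if (sp >= sd_up) return(c(sig, 0))
    dll <- sum(dnorm(x, 0, sp, log = TRUE)) -
      sum(dnorm(x, 0, sig, log = TRUE)) + (lsp - ls)
    if (is.finite(dll) && log(runif(1)) < dll) c(sp, 1) else c(sig, 0)
  }

  # --- storage ---
  par_names <- c(
    paste0("alpha[", prep$stages, "]"),
    if (J > 0) {
      idx <- which(ua, arr.ind = TRUE)
      paste0("beta[", colnames(X)[idx[, 1]], ",", prep$stages[idx[, 2]], "]")
    },
    if (beta_by_year) {
      idx <- which(ua, arr.ind = TRUE)
      unlist(lapply(seq_len(nrow(idx)), function(r) {
        paste0("delta[", colnames(X)[idx[r, 1]], ",",
               prep$stages[idx[r, 2]], ",", prep$years, "]")
      }))
    },
    "mu_p",
    if (det_re) c(paste0("eps[", prep$cells, "]"), "sigma_p"),
    if (site_re) c(paste0("u[", prep$sites, "]"), "sigma_site"),
    if (obs_re) c(paste0("eta[", seq_len(n), "]"), "sigma_obs"),
    if (beta_by_year) "sigma_beta"
  )
  draws <- matrix(NA_real_, n_save, length(par_names),
                  dimnames = list(NULL, par_names))
  model_draws <- if (mode == "models") {
    matrix(NA_integer_, n_save, S, dimnames = list(NULL, prep$stages))
  }
  incl_draws <- if (mode == "screen") {
    matrix(NA_integer_, n_save, G, dimnames = list(NULL, names(prep$groups)))
  }
  z_draws <- if (store_z) matrix(NA_integer_, n_save, n)
  z_sum <- numeric(n)
  ua_flat <- which(ua)

  save_row <- 0L
  for (it in seq_len(n_iter)) {
    a_mat <- active()

    # -- latent occupancy state --
    zl <- lpsi + 3 * plogis(lp_det, lower.tail = FALSE, log.p = TRUE)
    z <- as.integer(det | (runif(n) < plogis(zl)))

    # -- stage intercepts --
    for (s in seq_len(S)) {
      idx <- su[[s]]
      res <- mh(alpha[s], sc$alpha[s], function(prop) {
        d <- prop - alpha[s]
        sum(.ll_occ(lpsi[idx] + d, z[idx])) - sum(.ll_occ(lpsi[idx], z[idx]))
      }, lp_norm)
      if (res[2] == 1) {
        lpsi[idx] <- lpsi[idx] + (res[1] - alpha[s])
        alpha[s] <- res[1]
      }
      acc$alpha[s] <- acc$alpha[s] + res[2]; att$alpha[s] <- att$alpha[s] + 1
    }

    # -- coefficients (active: vs data; inactive: pseudoprior = prior) --
    for (s in seq_len(S)) {
      for (j in which(ua[, s])) {
        if (a_mat[j, s]) {
          idx <- su[[s]]
          xj <- X[idx, j]
          res <- mh(B[j, s], sc$beta[j, s], function(prop) {
            d <- (prop - B[j, s]) * xj
            sum(.ll_occ(lpsi[idx] + d, z[idx])) -
              sum(.ll_occ(lpsi[idx], z[idx]))
          }, lp_norm)
          if (res[2] == 1) {
            lpsi[idx] <- lpsi[idx] + (res[1] - B[j, s]) * xj
            B[j, s] <- res[1]
          }
          acc$beta[j, s] <- acc$beta[j, s] + res[2]
          att$beta[j, s] <- att$beta[j, s] + 1
        } else {
          B[j, s] <- rnorm(1, 0, bsd)
          if (beta_by_year) D[j, s, ] <- rnorm(prep$Y, 0, sigma_beta)
        }
        if (beta_by_year && a_mat[j, s]) {
          for (yy in seq_len(prep$Y)) {
            idx <- su[[s]][year_i[su[[s]]] == yy]
            if (!length(idx)) {
              D[j, s, yy] <- rnorm(1, 0, sigma_beta)
              next
            }
            xj <- X[idx, j]
            cur <- D[j, s, yy]
            prop <- cur + sc$delta[j, s] * rnorm(1)
            d <- (prop - cur) * xj
            lr <- sum(.ll_occ(lpsi[idx] + d, z[idx])) -
              sum(.ll_occ(lpsi[idx], z[idx])) +
              dnorm(prop, 0, sigma_beta, log = TRUE) -
              dnorm(cur, 0, sigma_beta, log = TRUE)
            if (is.finite(lr) && log(runif(1)) < lr) {
              lpsi[idx] <- lpsi[idx] + d
              D[j, s, yy] <- prop
              acc$delta[j, s] <- acc$delta[j, s] + 1
            }
            att$delta[j, s] <- att$delta[j, s] + 1
          }
        }
      }
    }
    if (beta_by_year) {
      # all year-level deviations that exist in the model (union-active)
      dall <- D[rep(ua_flat, times = prep$Y) +
                  rep((seq_len(prep$Y) - 1L) * J * S, each = length(ua_flat))]
      res <- mh_lsig(sigma_beta, sc$lsig[4], dall)
      sigma_beta <- res[1]
      acc$lsig[4] <- acc$lsig[4] + res[2]; att$lsig[4] <- att$lsig[4] + 1
    }

    # -- site random effects --
    if (site_re) {
      du <- sc$u * rnorm(prep$nsite)
      dl <- .ll_occ(lpsi + du[site_i], z) - .ll_occ(lpsi, z)
      by_site <- numeric(prep$nsite)
      tmp <- rowsum(dl, site_i)
      by_site[as.integer(rownames(tmp))] <- tmp
      lr <- by_site + dnorm(u + du, 0, sigma_site, log = TRUE) -
        dnorm(u, 0, sigma_site, log = TRUE)
      ok <- log(runif(prep$nsite)) < lr
      u[ok] <- u[ok] + du[ok]
      lpsi <- lpsi + (du * ok)[site_i]
      acc$u <- acc$u + ok; att$u <- att$u + 1
      res <- mh_lsig(sigma_site, sc$lsig[1], u)
      sigma_site <- res[1]
      acc$lsig[1] <- acc$lsig[1] + res[2]; att$lsig[1] <- att$lsig[1] + 1
    }

    # -- latent model indicator (cross-product selection) --
    if (mode == "models") {
      for (s in seq_len(S)) {
        inc <- prep$incl_list[[s]]
        M <- nrow(inc)
        idx <- su[[s]]
        base <- alpha[s] + (if (site_re) u[site_i[idx]] else 0)
        contrib <- NULL
        jset <- which(ua[, s])
        if (length(jset)) {
          contrib <- vapply(jset, function(j) X[idx, j] * coef_js(j, idx),
                            numeric(length(idx)))
          if (!is.matrix(contrib)) contrib <- matrix(contrib, nrow = length(idx))
        }
        ll <- vapply(seq_len(M), function(m) {
          lin <- base
          on <- which(inc[m, jset])
          if (length(on)) lin <- lin + rowSums(contrib[, on, drop = FALSE])
          sum(.ll_occ(lin, z[idx]))
        }, 0)
        pr <- exp(ll - max(ll))
        m_cur[s] <- sample.int(M, 1, prob = pr)
        lin <- base
        on <- which(inc[m_cur[s], jset])
        if (length(on)) lin <- lin + rowSums(contrib[, on, drop = FALSE])
        lpsi[idx] <- lin
      }
    }

    # -- Kuo-Mallick inclusion indicators (screening) --
    if (mode == "screen") {
      lodds0 <- qlogis(priors$inclusion_prior)
      for (g in sample.int(G)) {
        contrib <- numeric(n)
        for (j in prep$groups[[g]]) {
          contrib <- contrib + X[, j] * coef_js(j, seq_len(n))
        }
        lpsi0 <- lpsi - I_cur[g] * contrib
        dll <- sum(.ll_occ(lpsi0 + contrib, z)) - sum(.ll_occ(lpsi0, z))
        I_cur[g] <- as.integer(runif(1) < plogis(lodds0 + dll))
        lpsi <- lpsi0 + I_cur[g] * contrib
      }
    }

    # -- detection --
    d1 <- which(z == 1L)
    k1 <- k[d1]
    res <- mh(mu_p, sc$mu_p, function(prop) {
      d <- prop - mu_p
      sum(.ll_det(lp_det[d1] + d, k1)) - sum(.ll_det(lp_det[d1], k1))
    }, lp_norm)
    if (res[2] == 1) {
      lp_det <- lp_det + (res[1] - mu_p)
      mu_p <- res[1]
    }
    acc$mu_p <- acc$mu_p + res[2]; att$mu_p <- att$mu_p + 1

    if (det_re) {
      de <- sc$eps * rnorm(C)
      dl <- .ll_det(lp_det[d1] + de[cell_i[d1]], k1) - .ll_det(lp_det[d1], k1)
      by_cell <- numeric(C)
      if (length(d1)) {
        tmp <- rowsum(dl, cell_i[d1])
        by_cell[as.integer(rownames(tmp))] <- tmp
      }
      lr <- by_cell + dnorm(eps + de, 0, sigma_p, log = TRUE) -
        dnorm(eps, 0, sigma_p, log = TRUE)
      ok <- log(runif(C)) < lr
      eps[ok] <- eps[ok] + de[ok]
      lp_det <- lp_det + (de * ok)[cell_i]
      acc$eps <- acc$eps + ok; att$eps <- att$eps + 1
      res <- mh_lsig(sigma_p, sc$lsig[2], eps)
      sigma_p <- res[1]
      acc$lsig[2] <- acc$lsig[2] + res[2]; att$lsig[2] <- att$lsig[2] + 1
    }

    if (obs_re) {
      # occupied units: MH against the binomial likelihood; unoccupied
      # units contribute no detection information, full conditional = prior
      deta <- sc$eta * rnorm(n)
      lr <- .ll_det(lp_det + deta, k) - .ll_det(lp_det, k) +
        dnorm(eta + deta, 0, sigma_obs, log = TRUE) -
        dnorm(eta, 0, sigma_obs, log = TRUE)
      ok <- logical(n)
      ok[d1] <- log(runif(length(d1))) < lr[d1]
      eta_new <- eta + deta * ok
      off <- setdiff(seq_len(n), d1)
      eta_new[off] <- rnorm(length(off), 0, sigma_obs)
      lp_det <- lp_det + (eta_new - eta)
      eta <- eta_new
      acc$eta <- acc$eta + sum(ok[d1]); acc$eta_n <- acc$eta_n + length(d1)
      res <- mh_lsig(sigma_obs, sc$lsig[3], eta)
      sigma_obs <- res[1]
      acc$lsig[3] <- acc$lsig[3] + res[2]; att$lsig[3] <- att$lsig[3] + 1
    }

    # -- burn-in adaptation --
    if (it <= n_burn && it %% batch == 0L) {
      delta <- min(0.1, 1 / sqrt(it / batch))
      adapt <- function(scale, a, at) {
        rate <- ifelse(at > 0, a / at, 0.44)
        scale * exp(delta * sign(rate - 0.44))
      }
      sc$alpha <- adapt(sc$alpha, acc$alpha, att$alpha)
      sc$beta <- adapt(sc$beta, acc$beta, att$beta)
      sc$delta <- adapt(sc$delta, acc$delta, att$delta)
      sc$u <- adapt(sc$u, acc$u, att$u)
      sc$eps <- adapt(sc$eps, acc$eps, att$eps)
      sc$eta <- adapt(sc$eta, acc$eta, max(acc$eta_n, 1))
      sc$mu_p <- adapt(sc$mu_p, acc$mu_p, att$mu_p)
      sc$lsig <- adapt(sc$lsig, acc$lsig, att$lsig)
      acc <- list(alpha = rep(0, S), beta = matrix(0, max(J, 1), S),
                  delta = matrix(0, max(J, 1), S),
                  u = rep(0, prep$nsite), eps = rep(0, C),
                  eta = 0, eta_n = 0, mu_p = 0, lsig = rep(0, 4))
      att <- acc
    }

    # -- store --
    if (it > n_burn && (it - n_burn) %% thin == 0L) {
      save_row <- save_row + 1L
      row <- c(
        alpha,
        if (J > 0) B[ua_flat],
        if (beta_by_year) {
          as.vector(vapply(seq_along(ua_flat), function(r) {
            jj <- ((ua_flat[r] - 1) %% J) + 1
            ss <- ((ua_flat[r] - 1) %/% J) + 1
            D[jj, ss, ]
          }, numeric(prep$Y)))
        },
        mu_p,
        if (det_re) c(eps, sigma_p),
        if (site_re) c(u, sigma_site),
        if (obs_re) c(eta, sigma_obs),
        if (beta_by_year) sigma_beta
      )
      draws[save_row, ] <- row
      if (mode == "models") model_draws[save_row, ] <- m_cur
      if (mode == "screen") incl_draws[save_row, ] <- I_cur
      if (store_z) z_draws[save_row, ] <- z
      z_sum <- z_sum + z
    }
  }

  list(params = draws, model = model_draws, incl = incl_draws,
       z = z_draws, z_mean = z_sum / max(save_row, 1),
       scales = sc, seed = seed)
}
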