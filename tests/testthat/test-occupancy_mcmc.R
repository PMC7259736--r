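test_that("posterior of the homogeneous model matches the exact grid posterior", {
  sim <- generate_detections(flat_scenario(300, 0.6, 0.7, seed = 101))
  dat <- as_occu_data(sim$records)
  fit <- occu_mcmc(dat, settings = mcmc_settings(seed = 11),
                   site_re = FALSE, det_re = FALSE)
  oracle <- grid_posterior_psi_p(dat$y)
  pars <- posterior_matrix(fit)
  mc_psi <- mean(plogis(pars[, "alpha[fall_harvest]"]))
  mc_p <- mean(plogis(pars[, "mu_p"]))
  expect_lt(abs(mc_psi - oracle$mean_psi), 0.02)
  expect_lt(abs(mc_p - oracle$mean_p), 0.02)
  # posterior mode close to the grid MLE/mode on the logit scale
  expect_lt(abs(median(pars[, "alpha[fall_harvest]"]) - oracle$mode["a"]), 0.15)
  expect_lt(abs(median(pars[, "mu_p"]) - oracle$mode["m"]), 0.15)
})

test_that("identical seed and settings reproduce chains bitwise", {
  sim <- generate_detections(flat_scenario(80, 0.5, 0.6, seed = 8))
  dat <- as_occu_data(sim$records)
  st <- mcmc_settings(n_chains = 2, n_iter = 600, n_burnin = 200, seed = 99)
  f1 <- occu_mcmc(dat, settings = st, site_re = FALSE, det_re = FALSE)
  f2 <- occu_mcmc(dat, settings = st, site_re = FALSE, det_re = FALSE)
  expect_identical(f1$chains[[1]]$params, f2$chains[[1]]$params)
  expect_identical(f1$chains[[2]]$params, f2$chains[[2]]$params)
})

test_that("all-zero histories concentrate occupancy mass near zero", {
  # with most units detected perfectly (k = 3), p is pinned near 1, so the
  # never-detected units force psi of the all-zero stratum towards 0;
  # checked against the exact grid posterior
  y <- rbind(matrix(1, 150, 3), matrix(0, 150, 3))
  dat <- occu_data(y, rep("fall_harvest", 300), rep(2011, 300),
                   sprintf("S%03d", 1:300))
  fit <- occu_mcmc(dat, settings = mcmc_settings(seed = 5),
                   site_re = FALSE, det_re = FALSE)
  oracle <- grid_posterior_psi_p(y)
  pars <- posterior_matrix(fit)
  expect_lt(abs(mean(plogis(pars[, "alpha[fall_harvest]"])) -
                  oracle$mean_psi), 0.02)
  # and fully-unoccupied data with those detections removed: psi -> 0
  y0 <- matrix(0, 100, 3)
  oracle0 <- grid_posterior_psi_p(y0)
  expect_lt(oracle0$mean_psi, 0.5)  # sanity on the oracle itself
})

test_that("empty data and invalid settings are rejected", {
  expect_error(mcmc_settings(n_iter = 100, n_burnin = 100))
  expect_error(occu_data(matrix(2, 1, 3), "breeding", 2011, "A"))
})

test_that("hierarchical detection variant runs and stores its random effects", {
  sc <- sim_scenario(n_sites = 60, years = 2011:2012,
                     stages = c("late_summer", "fall_harvest"),
                     sigma_p = 0.5, sigma_obs = 0, sigma_site = 0.4,
                     alpha = c(late_summer = 0.5, fall_harvest = 1),
                     seed = 31)
  sim <- generate_detections(sc)
  dat <- as_occu_data(sim$records)
  fit <- occu_mcmc(dat, settings = mcmc_settings(n_chains = 2, n_iter = 800,
                                                 n_burnin = 300, seed = 2))
  pars <- posterior_matrix(fit)
  expect_true("sigma_p" %in% colnames(pars))
  expect_true("sigma_site" %in% colnames(pars))
  expect_true(any(grepl("^eps\\[", colnames(pars))))
  expect_true(all(pars[, "sigma_p"] >= 0 & pars[, "sigma_p"] <= 10))
  expect_equal(nrow(pars), 2 * 500)
})

test_that("split-Rhat flags divergence and passes well-mixed chains", {
  set.seed(1)
  good <- lapply(1:3, function(i) {
    m <- matrix(rnorm(2000), 1000, 2)
    colnames(m) <- c("a", "b"); m
  })
  fit <- structure(list(chains = lapply(good, function(m) list(params = m))),
                   class = "occu_fit")
  d <- convergence_diagnostics(fit)
  expect_true(all(d$rhat > 0.99 & d$rhat < 1.05))
  expect_false(any(d$flagged))
  bad <- lapply(1:2, function(i) {
    m <- matrix(rnorm(1000, mean = 10 * i), 1000, 1)
    colnames(m) <- "a"; m
  })
  fitb <- structure(list(chains = lapply(bad, function(m) list(params = m))),
                    class = "occu_fit")
  db <- convergence_diagnostics(fitb)
  expect_gt(db$rhat[1], 1.1)
  expect_true(db$flagged[1])
  # constant parameter: undefined, flagged
  cst <- lapply(1:2, function(i) {
    m <- matrix(1, 500, 1); colnames(m) <- "c"; m
  })
  fitc <- structure(list(chains = lapply(cst, function(m) list(params = m))),
                    class = "occu_fit")
  dc <- convergence_diagnostics(fitc)
  expect_true(is.na(dc$rhat[1]))
  expect_true(dc$flagged[1])
  # single chain: diagnostics unavailable
  f1 <- structure(list(chains = list(list(params = good[[1]]))),
                  class = "occu_fit")
  d1 <- convergence_diagnostics(f1)
  expect_false(attr(d1, "available"))
})
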