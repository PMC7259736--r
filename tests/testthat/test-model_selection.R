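test_that("candidate sets enforce the pair rule and stage availability", {
  expect_error(candidate_model("bad", "cone_density"), NA)  # checked at fit time
  sets <- final_candidate_sets()
  expect_equal(vapply(sets$fall_harvest, function(m) m$name, ""),
               c("M1", "M2", "M3", "M5"))
  expect_equal(vapply(sets$breeding, function(m) m$name, ""),
               c("M1", "M3", "M4", "M6"))
  expect_equal(vapply(sets$early_summer, function(m) m$name, ""),
               c("M1", "M3"))
  expect_error(candidate_model("int", c("a:b"),
                               interactions = list("a:b" = c("a", "b"))),
               "main effects")
})

test_that("selection summaries are frequency counts with conditional estimates", {
  # hand-built 10-draw chain over {M1, M2}, M2 = {x}
  X <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "x"))
  incl <- matrix(c(FALSE, TRUE), 2, 1, dimnames = list(NULL, "x"))
  params <- cbind(
    "alpha[fall_harvest]" = rep(0, 10),
    "beta[x,fall_harvest]" = c(5, -2, 1, 2, 3, 9, 4, 5, 6, -7)
  )
  model <- matrix(c(1, 1, 2, 2, 2, 1, 2, 2, 2, 1), ncol = 1,
                  dimnames = list(NULL, "fall_harvest"))
  fit <- fake_fit(params, "fall_harvest", X, model = model,
                  incl_list = list(incl), model_names = list(c("M1", "M2")))
  s <- summarize_selection(fit)
  expect_equal(unname(s$fall_harvest$model_probs), c(0.4, 0.6))
  expect_equal(sum(s$fall_harvest$model_probs), 1)
  expect_equal(unname(s$fall_harvest$inclusion["x"]), 0.6)
  # conditional mean over the draws where x is in the model
  inc_draws <- model[, 1] == 2
  expect_equal(s$fall_harvest$conditional$mean,
               mean(params[inc_draws, "beta[x,fall_harvest]"]))
  # indicator chain (1,1,2,2): probabilities (0.5, 0.5)
  model2 <- matrix(c(1L, 1L, 2L, 2L), ncol = 1,
                   dimnames = list(NULL, "fall_harvest"))
  fit2 <- fake_fit(params[1:4, , drop = FALSE], "fall_harvest", X,
                   model = model2, incl_list = list(incl),
                   model_names = list(c("M1", "M2")))
  s2 <- summarize_selection(fit2)
  expect_equal(unname(s2$fall_harvest$model_probs), c(0.5, 0.5))
})

test_that("inclusion probability equals the summed probability of containing models", {
  sc <- flat_scenario(150, 0.7, 0.6, seed = 55,
                      beta = list(fall_harvest = c(wbp_area = 1.2)))
  sim <- generate_detections(sc)
  dat <- as_occu_data(sim$records, sim$X[, c("wbp_area", "df_area")])
  sets <- list(fall_harvest = list(
    candidate_model("M1"),
    candidate_model("M3", "wbp_area"),
    candidate_model("M4", "df_area"),
    candidate_model("M6", c("wbp_area", "df_area"))
  ))
  fit <- occu_mcmc(dat, model_sets = sets,
                   settings = mcmc_settings(n_chains = 2, n_iter = 1500,
                                            n_burnin = 500, seed = 3),
                   site_re = FALSE, det_re = FALSE)
  s <- summarize_selection(fit)
  p <- s$fall_harvest$model_probs
  expect_equal(sum(p), 1)
  expect_equal(unname(s$fall_harvest$inclusion["wbp_area"]),
               unname(p["M3"] + p["M6"]))
  expect_equal(unname(s$fall_harvest$inclusion["df_area"]),
               unname(p["M4"] + p["M6"]))
  tab <- model_prob_table(s)
  expect_equal(unname(unlist(tab["fall_harvest", ])), unname(p))
})

test_that("duplicate candidate models split the posterior symmetrically", {
  sim <- generate_detections(flat_scenario(100, 0.6, 0.6, seed = 12))
  dat <- as_occu_data(sim$records)
  sets <- list(fall_harvest = list(candidate_model("A"), candidate_model("B")))
  fit <- occu_mcmc(dat, model_sets = sets,
                   settings = mcmc_settings(seed = 21),
                   site_re = FALSE, det_re = FALSE)
  s <- summarize_selection(fit)
  expect_lt(abs(s$fall_harvest$model_probs[["A"]] - 0.5), 0.05)
  # single-model set: probability exactly 1
  fit1 <- occu_mcmc(dat, model_sets = list(fall_harvest =
                                             list(candidate_model("only"))),
                    settings = mcmc_settings(n_iter = 500, n_burnin = 100,
                                             n_chains = 1, seed = 2),
                    site_re = FALSE, det_re = FALSE)
  s1 <- summarize_selection(fit1)
  expect_equal(unname(s1$fall_harvest$model_probs), 1)
})

test_that("zero-inflated pairs may only enter candidate models together", {
  sc <- flat_scenario(40, 0.5, 0.6, seed = 1)
  sim <- generate_detections(sc)
  dat <- as_occu_data(sim$records,
                      design_subset(sim$X, c("cone_density_absent",
                                             "cone_density")))
  bad <- list(fall_harvest = list(candidate_model("M1"),
                                  candidate_model("Mx", "cone_density")))
  expect_error(occu_mcmc(dat, model_sets = bad), "together")
  expect_error(design_subset(sim$X, "cone_density"), "together")
})

test_that("screening retains a strong covariate and drops pure noise", {
  sc <- flat_scenario(300, 0.6, 0.65, seed = 14,
                      beta = list(fall_harvest = c(wbp_area = 1.5)))
  sim <- generate_detections(sc)
  dat <- as_occu_data(sim$records, sim$X[, c("wbp_area", "df_area")])
  out <- screen_covariates(dat,
                           settings = mcmc_settings(n_chains = 2,
                                                    n_iter = 2000,
                                                    n_burnin = 800, seed = 6),
                           site_re = FALSE, det_re = FALSE)
  pip <- setNames(out$inclusion$inclusion_prob, out$inclusion$group)
  expect_gt(pip[["wbp_area"]], 0.8)
  expect_true("wbp_area" %in% out$retained)
  expect_false("df_area" %in% out$retained)  # noise covariate
})
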