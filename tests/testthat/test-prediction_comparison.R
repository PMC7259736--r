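make_pred_fit <- function(alpha_draws, beta_draws, X) {
  params <- cbind("alpha[fall_harvest]" = alpha_draws,
                  "beta[wbp_area,fall_harvest]" = beta_draws)
  fake_fit(params, "fall_harvest", X)
}

pred_X <- function() {
  covs <- data.frame(wbp_area = c(10000, 20000, 30000, 40000, 50000))
  build_design(covs, continuous = "wbp_area")
}

test_that("flat-coefficient posteriors give flat curves at the intercept", {
  X <- pred_X()
  fit <- make_pred_fit(rep(qlogis(0.7), 50), rep(0, 50), X)
  cv <- predict_psi(fit, "fall_harvest", "wbp_area", n_grid = 20)
  expect_true(all(abs(cv$mean - 0.7) < 1e-12))
  expect_true(all(cv$lower <= cv$mean & cv$mean <= cv$upper))
})

test_that("positive coefficients give non-decreasing mean curves", {
  X <- pred_X()
  set.seed(9)
  fit <- make_pred_fit(rnorm(200, 0, 0.5), runif(200, 0.2, 1.5), X)
  cv <- predict_psi(fit, "fall_harvest", "wbp_area", n_grid = 50)
  expect_true(all(diff(cv$mean) >= -1e-12))
  expect_true(all(cv$mean >= 0 & cv$mean <= 1))
})

test_that("credible bounds equal hand-computed order statistics", {
  X <- pred_X()
  a <- c(-1, 0, 0.5, 1); b <- c(0.2, -0.1, 0.4, 0.8)
  fit <- make_pred_fit(a, b, X)
  grid <- c(15000, 30000, 45000)
  cv <- predict_psi(fit, "fall_harvest", "wbp_area", grid = grid)
  gs <- (grid - attr(X, "center")[["wbp_area"]]) /
    attr(X, "scale")[["wbp_area"]]
  for (g in 1:3) {
    psi <- plogis(a + b * gs[g])
    expect_equal(cv$mean[g], mean(psi))
    s <- sort(psi)
    # type-7 order-statistic interpolation at 2.5% and 97.5% for n = 4
    expect_equal(cv$lower[g], s[1] + 0.075 * (s[2] - s[1]), tolerance = 1e-12)
    expect_equal(cv$upper[g], s[3] + 0.925 * (s[4] - s[3]), tolerance = 1e-12)
  }
  expect_error(predict_psi(fit, "fall_harvest", "nope"), "unknown")
  expect_error(predict_psi(fit, "fall_harvest", "wbp_area",
                           conditioning = list(zzz = 1)), "unknown")
})

test_that("model-averaged curves are transform-consistent in original units", {
  # same covariate, two standardizations: curves on an original-unit grid
  # must agree because coefficients adapt to the scale used
  covs1 <- data.frame(wbp_area = c(10000, 20000, 30000, 40000, 50000))
  X1 <- build_design(covs1, continuous = "wbp_area")
  b1 <- 0.8
  # re-standardize after doubling the spread of the sample used for scaling
  covs2 <- data.frame(wbp_area = c(0, 15000, 30000, 45000, 60000))
  X2 <- build_design(covs2, continuous = "wbp_area")
  scale_ratio <- attr(X2, "scale")[["wbp_area"]] /
    attr(X1, "scale")[["wbp_area"]]
  center_shift <- (attr(X1, "center")[["wbp_area"]] -
                     attr(X2, "center")[["wbp_area"]]) /
    attr(X2, "scale")[["wbp_area"]]
  # equivalent model on the second scale
  b2 <- b1 * scale_ratio
  a2 <- 0 + b2 * center_shift
  f1 <- make_pred_fit(rep(0, 10), rep(b1, 10), X1)
  f2 <- make_pred_fit(rep(a2, 10), rep(b2, 10), X2)
  grid <- seq(12000, 48000, length.out = 7)
  c1 <- predict_psi(f1, "fall_harvest", "wbp_area", grid = grid)
  c2 <- predict_psi(f2, "fall_harvest", "wbp_area", grid = grid)
  expect_equal(c1$mean, c2$mean, tolerance = 1e-10)
})

test_that("threshold finding interpolates linearly and respects monotonicity", {
  cv <- data.frame(value = c(10000, 20000), mean = c(0.6, 0.8))
  expect_equal(threshold_area(cv, 0.75), 17500)
  flat <- data.frame(value = c(0, 1, 2), mean = rep(0.5, 3))
  expect_true(is.na(threshold_area(flat, 0.75)))
  high <- data.frame(value = c(5, 10), mean = c(0.9, 0.95))
  expect_equal(threshold_area(high, 0.75), 5)
  expect_error(threshold_area(cv, 1.5), "probability")
  wavy <- data.frame(value = 1:4, mean = c(0.2, 0.8, 0.4, 0.9))
  expect_warning(th <- threshold_area(wavy, 0.75), "monotone")
  expect_lt(th, 2)
  # non-decreasing in the target for a monotone curve
  mono <- data.frame(value = seq(0, 100, 10),
                     mean = plogis(seq(-3, 3, length.out = 11)))
  ths <- vapply(c(0.3, 0.5, 0.7, 0.9), function(t) threshold_area(mono, t), 0)
  expect_true(all(diff(ths) > 0))
})

test_that("published comparator formulas evaluate exactly", {
  expect_equal(mckinney_predict(0), -0.449)
  expect_equal(mckinney_predict(0.449 / 0.019), 0)
  expect_equal(mckinney_predict(100), 1.451)
  expect_equal(mckinney_predict(100, clip = TRUE), 1)
  expect_equal(barringer_predict(0), plogis(-1.5165), tolerance = 1e-12)
  expect_equal(barringer_predict(0), 0.1799775, tolerance = 1e-6)
  x <- seq(0, 300, 1)
  bp <- barringer_predict(x)
  expect_true(all(bp > 0 & bp < 1))
  expect_true(all(diff(bp) > 0))          # strictly increasing
  mp <- mckinney_predict(x)
  expect_equal(unique(round(diff(mp), 12)), 0.019)  # affine, slope 0.019
  expect_gt(barringer_predict(1e6), 0.999)
})

test_that("comparator filter reproduces the published data restrictions", {
  df <- data.frame(
    radius_class = c("infinite", "within_100m", "infinite", "infinite",
                     "infinite"),
    date = as.Date(c("2013-08-20", "2013-08-20", "2013-07-01",
                     "2013-09-01", "2013-09-01")),
    cone_density = c(100, 100, 100, 0, 50),
    cone_count_date = as.Date(c("2013-08-20", "2013-08-20", "2013-07-01",
                                "2013-09-01", "2013-08-30"))
  )
  out <- comparator_filter(df)
  expect_equal(nrow(out), 1)  # only row 1 satisfies all four conditions
  expect_equal(out$date, as.Date("2013-08-20"))
})

test_that("observed-vs-predicted comparison handles ranks, ties and zeros", {
  obs <- c(0.9, 0.8, 0.7, 0.9, 1, 0.8, 0.7, 0.9, 1, 0.8)
  pred <- obs - 0.2                       # strictly underpredicting
  cmp <- compare_observed_predicted(obs, pred)
  expect_equal(cmp$W, 55)                 # all 10 signed ranks positive
  expect_lt(cmp$W_p, 0.01)
  expect_equal(cmp$rho, 1)
  same <- compare_observed_predicted(obs, obs)
  expect_equal(same$rho, 1)
  expect_true(is.na(same$W))
  expect_match(same$note, "undefined")
  anti <- compare_observed_predicted(1:6 / 10, 6:1 / 10)
  expect_equal(anti$rho, -1)
  expect_error(compare_observed_predicted(1:3, 3:1), "at least 5")
  expect_error(cone_index(c(0, 10)))
  expect_equal(cone_index(exp(2)), 4)
  expect_equal(cone_index(100, base = "log10"), 4)
})
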