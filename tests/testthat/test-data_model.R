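test_that("dates map to the unique containing stage and winter is rejected", {
  w <- stage_windows(2011)
  expect_equal(assign_stage(as.Date("2011-03-10"), w), "breeding")
  expect_equal(assign_stage(as.Date("2011-06-15"), w), "breeding")
  expect_equal(assign_stage(as.Date("2011-06-16"), w), "early_summer")
  expect_error(assign_stage(as.Date("2011-02-01"), w), "outside")
  # year-specific phenological boundaries are honoured
  w2 <- stage_windows(2011, boundaries = list(
    early_summer = c("06-16", "06-30"), late_summer = c("07-01", "08-11")))
  expect_equal(assign_stage(as.Date("2011-07-05"), w2), "late_summer")
  # overlapping windows are refused
  expect_error(stage_windows(2011, boundaries = list(
    early_summer = c("06-10", "07-11"))), "overlap")
})

test_that("first-visit filter keeps the earliest record per unit and is idempotent", {
  df <- rbind(
    make_survey_df(date = "2011-08-25", counts = c(1, 0, 0)),
    make_survey_df(date = "2011-08-20", counts = c(0, 1, 0)),
    make_survey_df(site = "B", date = "2011-08-22"),
    make_survey_df(date = "2012-08-21", year = 2012)  # other year retained
  )
  out <- first_visit_filter(df)
  expect_equal(nrow(out), 3)
  expect_equal(out$date[out$site_id == "A" & out$year == 2011],
               as.Date("2011-08-20"))
  expect_identical(first_visit_filter(out), out)
  # single record untouched
  one <- make_survey_df()
  expect_identical(first_visit_filter(one), one)
})

test_that("radius consistency rejects 100m detections missing at infinite radius", {
  ok <- rbind(make_survey_df(counts = c(0, 1, 0), radius = "within_100m"),
              make_survey_df(counts = c(1, 1, 0), radius = "infinite"))
  expect_equal(nrow(check_radius_consistency(ok)), 0)
  expect_s3_class(validate_surveys(ok), "data.frame")
  bad <- rbind(make_survey_df(counts = c(1, 0, 0), radius = "within_100m"),
               make_survey_df(counts = c(0, 1, 0), radius = "infinite"))
  expect_equal(nrow(check_radius_consistency(bad)), 1)
  expect_error(validate_surveys(bad), "radius inconsistency")
})

test_that("naive metrics agree with hand computation and with each other", {
  m <- naive_metrics(rbind(c(0, 0, 0), c(1, 0, 1), c(0, 1, 0), c(1, 1, 1)))
  expect_equal(m$naive_occurrence, c(0, 1, 1, 1))
  expect_equal(m$proportion_detected, c(0, 2 / 3, 1 / 3, 1))
  # property: naive occurrence is 1 iff any time was detected
  set.seed(11)
  h <- matrix(rbinom(300, 1, 0.4), ncol = 3)
  mm <- naive_metrics(h)
  expect_equal(mm$naive_occurrence == 1, mm$proportion_detected > 0)
})

test_that("survey schedule tally reproduces the published sample sizes", {
  sched <- read.csv(system.file("extdata", "survey_schedule_gye.csv",
                                package = "occuselect"))
  tt <- tally_surveys(sched)
  expect_equal(tt$total, 2526)
  expect_equal(unname(tt$by_stage["breeding"]), 384)
  expect_equal(unname(tt$by_stage["late_summer"]), 753)
  empty <- tally_surveys(sched[0, ])
  expect_equal(empty$total, 0)
  expect_true(all(empty$by_stage == 0))
})

test_that("z-scores have mean 0, sample sd 1, and reject degenerate input", {
  z <- zscore(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_error(zscore(rep(2, 5)), "constant")
  expect_error(zscore(numeric(0)))
  set.seed(3)
  for (i in 1:10) {
    z <- zscore(rnorm(50, sd = runif(1, 0.1, 10)))
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(sd(z) - 1), 1e-10)
    # idempotence
    expect_equal(as.numeric(zscore(as.numeric(z))), as.numeric(z),
                 tolerance = 1e-12)
  }
})

test_that("zero-inflated decomposition standardizes over positives only", {
  d <- decompose_zero_inflated(c(0, 10, 20))
  expect_equal(d$absence, c(1, 0, 0))
  expect_equal(d$magnitude, c(0, -sqrt(0.5), sqrt(0.5)))
  all_pos <- decompose_zero_inflated(c(3, 1, 2))
  expect_true(all(all_pos$absence == 0))
  degenerate <- decompose_zero_inflated(c(0, 0, 0))
  expect_false(degenerate$magnitude_defined)
  expect_equal(degenerate$absence, c(1, 1, 1))
  expect_error(decompose_zero_inflated(c(-1, 2)), "non-negative")
})

test_that("design matrix columns carry standardization metadata", {
  covs <- data.frame(cone_density = c(0, 0, 50, 400, 900),
                     wbp_area = c(1e4, 2e4, 4e4, 6e4, 8e4))
  X <- build_design(covs, continuous = "wbp_area",
                    zero_inflated = "cone_density")
  expect_setequal(colnames(X), c("wbp_area", "cone_density_absent",
                                 "cone_density"))
  expect_lt(abs(mean(X[, "wbp_area"])), 1e-10)
  expect_equal(X[, "cone_density_absent"], c(1, 1, 0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(X[X[, "cone_density_absent"] == 1, "cone_density"], c(0, 0),
               ignore_attr = TRUE)
  expect_equal(attr(X, "zi_pairs")$cone_density,
               c("cone_density_absent", "cone_density"))
  # mapping a grid value back through the metadata is exact
  v <- 400
  expect_equal((v - attr(X, "center")[["cone_density"]]) /
                 attr(X, "scale")[["cone_density"]],
               X[4, "cone_density"], ignore_attr = TRUE)
})
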