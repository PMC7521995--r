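test_that("breast-outcome censoring follows the first-event rule", {
  co <- toy_cohort(
    toy_carrier(age_bc = 45, age_mastectomy = 40),          # surgery first
    toy_carrier(age_last_followup = 85),                    # administrative 80
    toy_carrier(age_bc = 45),                               # event
    toy_carrier(age_oc = 38, age_bc = 45,
                age_last_followup = 85),                    # ovarian censors
    toy_carrier(age_bc = 50, age_mastectomy = 50))          # tie: event wins
  ds <- build_analysis_dataset(co, "breast")
  expect_equal(ds$exit_age, c(40, 80, 45, 38, 50))
  expect_equal(ds$event, c(0L, 0L, 1L, 0L, 1L))
  expect_true(all(ds$entry_age == 0))
})

test_that("ER-specific outcomes censor the opposite subtype and drop missing ER", {
  co <- toy_cohort(
    toy_carrier(age_bc = 50, er_status = "positive"),
    toy_carrier(age_bc = 45, er_status = "negative"),
    toy_carrier(age_bc = 40),                               # ER missing
    toy_carrier())                                          # unaffected
  neg <- build_analysis_dataset(co, "er_negative")
  expect_equal(nrow(neg), 3L)                               # missing-ER excluded
  expect_equal(neg$event[neg$exit_age == 50], 0L)           # ER+ censors at 50
  expect_equal(neg$event[neg$exit_age == 45], 1L)
  pos <- build_analysis_dataset(co, "er_positive")
  expect_equal(pos$event[pos$exit_age == 50], 1L)
  expect_equal(pos$event[pos$exit_age == 45], 0L)
})

test_that("ovarian outcome censors at RRSO and optionally at breast cancer", {
  co <- toy_cohort(
    toy_carrier(age_oc = 55, age_rrso = 48),
    toy_carrier(age_oc = 55, age_mastectomy = 40),          # mastectomy ignored
    toy_carrier(age_bc = 45, age_oc = 55))
  ds <- build_analysis_dataset(co, "ovarian")
  expect_equal(ds$exit_age, c(48, 55, 45))
  expect_equal(ds$event, c(0L, 1L, 0L))
  ds2 <- build_analysis_dataset(co, "ovarian", censor_ovarian_at_bc = FALSE)
  expect_equal(ds2$exit_age[3], 55)
  expect_equal(ds2$event[3], 1L)
})

test_that("prospective mode uses delayed entry and drops prevalent cases", {
  co <- toy_cohort(
    toy_carrier(age_recruit = 40, age_bc = 35,
                age_last_followup = 50),                    # prevalent: excluded
    toy_carrier(age_recruit = 40, age_bc = 45),             # incident event
    toy_carrier(age_recruit = 40))                          # censored at follow-up
  ds <- build_analysis_dataset(co, "breast", mode = "prospective")
  expect_equal(nrow(ds), 2L)
  expect_equal(ds$entry_age, c(40, 40))
  expect_equal(ds$event, c(1L, 0L))
})

test_that("event after last follow-up is a validation error naming the carrier", {
  expect_error(toy_cohort(toy_carrier(age_bc = 75, age_last_followup = 70)),
               "age_bc")
})

test_that("sampling-weight calibration reproduces the stated p/q formula", {
  # one bin [40,45): 1 affected among 10 exits gives q = 0.10; a flat external
  # hazard chosen so the expected event count is 0.5 gives p = 0.05
  time <- c(44, rep(seq(40.5, 44.5, length.out = 9), 1))
  status <- c(1, rep(0, 9))
  ds <- toy_dataset(time, status, z = rnorm(10))
  pt <- sum(time - 40)                 # person-time inside the bin
  lam <- 0.5 / pt
  cal <- calibrate_sampling_weights(ds, incidence_curve(0, 45, lam),
                                    age_bins = c(40, 45))
  expect_equal(cal$scheme$observed_fraction, 0.10)
  expect_equal(cal$scheme$target_fraction, 0.05, tolerance = 1e-12)
  expect_equal(cal$scheme$weight_affected, 0.5, tolerance = 1e-12)
  expect_equal(cal$scheme$weight_unaffected, 0.95 / 0.90, tolerance = 1e-12)
  expect_equal(cal$dataset$sampling_weight, c(0.5, rep(0.95 / 0.90, 9)))
})

test_that("already representative cohorts get unit weights", {
  time <- c(44, rep(seq(40.5, 44.5, length.out = 9), 1))
  status <- c(1, rep(0, 9))
  ds <- toy_dataset(time, status, z = rnorm(10))
  lam <- 1 / sum(time - 40)            # expected events = observed = 1
  cal <- calibrate_sampling_weights(ds, incidence_curve(0, 45, lam),
                                    age_bins = c(40, 45))
  expect_equal(cal$scheme$weight_affected, 1, tolerance = 1e-12)
  expect_equal(cal$scheme$weight_unaffected, 1, tolerance = 1e-12)
})

test_that("calibration errors on empty or degenerate bins", {
  ds <- toy_dataset(c(44, 44.5), c(1, 0), z = c(0, 0))
  expect_error(
    calibrate_sampling_weights(ds, incidence_curve(0, 50, 0.01),
                               age_bins = c(30, 40, 45)),
    "coarser")
  ds2 <- toy_dataset(c(44, 44.5), c(1, 1), z = c(0, 0))
  expect_error(
    calibrate_sampling_weights(ds2, incidence_curve(0, 50, 0.001),
                               age_bins = c(40, 45)),
    "0 or 1")
})

test_that("calibrated weights equalise the weighted affected fraction to p exactly", {
  sim <- simulate_retrospective_cohort(default_sim_config(n = 4000, seed = 21L))
  cur <- make_incidence_fixture(0.72, "breast")
  ds <- build_analysis_dataset(sim$cohort, "breast")
  bins <- c(18, seq(30, 70, 10), 80)
  cal <- calibrate_sampling_weights(ds, cur, age_bins = bins)
  b <- pmin(findInterval(cal$dataset$exit_age, bins), length(bins) - 1L)
  for (j in seq_len(length(bins) - 1L)) {
    sel <- b == j
    wf <- sum(cal$dataset$sampling_weight[sel & cal$dataset$event == 1]) /
      sum(cal$dataset$sampling_weight[sel])
    expect_equal(wf, cal$scheme$target_fraction[j], tolerance = 1e-12)
  }
})

test_that("weighting restores the external age-specific incidence", {
  # heavily ascertained cohort; weighted events / weighted person-time per
  # decade should track the generating curve, unweighted should not
  cur <- make_incidence_fixture(0.72, "breast")
  sim <- simulate_retrospective_cohort(default_sim_config(n = 8000, seed = 31L))
  ds <- build_analysis_dataset(sim$cohort, "breast")
  cal <- calibrate_sampling_weights(ds, cur,
                                    age_bins = c(18, seq(30, 70, 10), 80))
  dsw <- cal$dataset
  dec <- cbind(c(25, 35, 45, 55), c(35, 45, 55, 65))
  for (r in seq_len(nrow(dec))) {
    lo <- dec[r, 1]; hi <- dec[r, 2]
    pt <- pmax(pmin(dsw$exit_age, hi) - lo, 0)
    ev <- dsw$event == 1 & dsw$exit_age >= lo & dsw$exit_age < hi
    rate_w <- sum(dsw$sampling_weight[ev]) / sum(dsw$sampling_weight * pt)
    lam_true <- (cumulative_hazard(cur, hi) - cumulative_hazard(cur, lo)) / (hi - lo)
    se <- sqrt(sum(dsw$sampling_weight[ev]^2)) / sum(dsw$sampling_weight * pt)
    expect_lt(abs(rate_w - lam_true), max(3 * se, 0.15 * lam_true))
  }
})
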