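test_that("three-subject fit matches the closed-form score solution", {
  # events at t=1 (z=1), t=2 (z=0), censored t=3 (z=1): the score equation
  # 1 = 2x/(2x+1) + x/(1+x), x = exp(beta), solves to beta = -log(2)/2
  ds <- toy_dataset(time = c(1, 2, 3), status = c(1, 1, 0), z = c(1, 0, 1))
  fit <- fit_weighted_cox(ds)
  expect_equal(unname(fit$coefficients["prs"]), -0.5 * log(2), tolerance = 1e-6)
  expect_equal(brute_cox_mle(c(1, 2, 3), c(1, 1, 0), c(1, 0, 1)),
               -0.5 * log(2), tolerance = 1e-6)
})

test_that("small weighted fits agree with brute-force likelihood maximisation", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 6
    time <- sort(runif(n, 1, 10))        # untied
    status <- rbinom(n, 1, 0.7)
    if (sum(status) == 0) status[1] <- 1
    z <- rnorm(n)
    w <- runif(n, 0.5, 2)
    ds <- toy_dataset(time, status, z, w = w)
    fit <- fit_weighted_cox(ds, ties = "breslow")
    expect_equal(unname(fit$coefficients["prs"]),
                 brute_cox_mle(time, status, z, w), tolerance = 1e-6)
  }
})

test_that("PRS permuted against outcomes estimates a null hazard ratio", {
  sim <- simulate_retrospective_cohort(default_sim_config(n = 2000, seed = 5L))
  ds <- build_analysis_dataset(sim$cohort, "breast")
  set.seed(99)
  ds$prs <- sample(ds$prs)
  fit <- fit_weighted_cox(ds)
  se <- sqrt(fit$robust_covariance[1, 1])
  expect_lt(abs(fit$coefficients["prs"]), 3.5 * se)
})

test_that("collinear covariates are rejected before fitting", {
  ds <- toy_dataset(1:6, rep(1, 6), rnorm(6))
  ds$prs2 <- 2 * ds$prs
  expect_error(fit_weighted_cox(ds, covariates = c("prs", "prs2")), "rank")
})

test_that("likelihood ratio test handles identical, nested and non-nested fits", {
  set.seed(12)
  n <- 120
  ds <- toy_dataset(runif(n, 30, 70), rbinom(n, 1, 0.5), rnorm(n))
  ds$x2 <- rnorm(n)
  f1 <- fit_weighted_cox(ds, covariates = "prs")
  f2 <- fit_weighted_cox(ds, covariates = c("prs", "x2"))
  same <- likelihood_ratio_test(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  lrt <- likelihood_ratio_test(f1, f2)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$statistic, 0)
  expect_error(likelihood_ratio_test(f2, f1), "nested|fewer")
})

test_that("the null LRT statistic is chi-square with one degree of freedom", {
  set.seed(77)
  stats_null <- replicate(400, {
    n <- 80
    ds <- toy_dataset(runif(n, 30, 70), rbinom(n, 1, 0.5), rnorm(n))
    ds$x2 <- rnorm(n)       # independent of outcome: null interaction stand-in
    f1 <- fit_weighted_cox(ds, covariates = "prs")
    f2 <- fit_weighted_cox(ds, covariates = c("prs", "x2"))
    max(0, 2 * (f2$loglik[2] - f1$loglik[2]))
  })
  ks <- suppressWarnings(stats::ks.test(stats_null, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("group-specific hazard ratios recover simulated heterogeneity", {
  set.seed(41)
  n <- 6000
  grp <- rep(c("g1", "g2"), each = n / 2)
  z <- rnorm(n)
  beta <- ifelse(grp == "g1", log(1.25), log(1.25) + 0.3)
  t_event <- rexp(n, 0.02 * exp(beta * z))
  cens <- runif(n, 10, 60)
  time <- pmin(t_event, cens)
  ds <- toy_dataset(time, as.integer(t_event <= cens), z)
  ds$group <- grp
  res <- interaction_models(ds, "group")
  b <- log(res$per_group$hr)
  expect_equal(b[1], log(1.25), tolerance = 3 * 0.05)
  expect_equal(b[2], log(1.25) + 0.3, tolerance = 3 * 0.05)
  expect_lt(res$lrt$p, 0.05)
  expect_lt(res$wald_p, 0.05)
  expect_error(interaction_models(transform(ds, group = "g1"), "group"),
               "single")
})

test_that("homogeneous groups do not trigger the heterogeneity test", {
  set.seed(42)
  n <- 2000
  z <- rnorm(n)
  t_event <- rexp(n, 0.02 * exp(log(1.3) * z))
  cens <- runif(n, 10, 60)
  ds <- toy_dataset(pmin(t_event, cens), as.integer(t_event <= cens), z)
  ds$group <- rep(c("g1", "g2"), each = n / 2)
  res <- interaction_models(ds, "group")
  expect_gt(res$lrt$p, 0.01)
})

test_that("categorical-percentile fits use the 40-60 reference and the
           truncated-normal expected curve", {
  sim <- simulate_retrospective_cohort(default_sim_config(n = 6000, seed = 13L))
  cur <- make_incidence_fixture(0.72, "breast")
  ds <- build_analysis_dataset(sim$cohort, "breast")
  ds <- calibrate_sampling_weights(ds, cur)$dataset
  pv <- structure(list(carrier_ids = ds$carrier_id, raw = ds$prs,
                       standardized = ds$prs, reference_sd = 1,
                       reference_mean = 0), class = "prs_vector")
  pc <- assign_percentiles(pv, ds$carrier_id[ds$event == 0])
  res <- categorical_percentile_fit(ds, pc$category, pc$scheme)
  expect_equal(res$per_bin$hr[pc$scheme$reference_bin], 1)
  # expected-HR curve: top bin at exp(beta * (E[z|top5%] - E[z|40-60]))
  mix <- discretize_standard_normal(pc$scheme$bin_edges)
  expect_equal(mix$representative_z[9], dnorm(qnorm(0.95)) / 0.05,
               tolerance = 1e-10)
  beta <- res$continuous_fit$coefficients["prs"]
  expect_equal(res$per_bin$expected_hr_continuous[9],
               unname(exp(beta * (mix$representative_z[9] -
                                    mix$representative_z[5]))),
               tolerance = 1e-12)
  # estimated bin HRs increase with PRS under a positive continuous effect
  expect_gt(res$per_bin$hr[9], res$per_bin$hr[1])
  # adding categories over the continuous score should not fit much better
  expect_gt(res$lrt$p, 0.001)
})

test_that("concordance matches exhaustive pair counting and its bounds", {
  set.seed(19)
  n <- 20
  time <- runif(n, 30, 70)
  status <- rbinom(n, 1, 0.6)
  score <- rnorm(n)
  ds <- toy_dataset(time, status, score)
  res <- concordance_index(ds, score)
  expect_equal(res$c_statistic,
               brute_concordance(rep(0, n), time, status, score),
               tolerance = 1e-12)

  # a score that perfectly orders event times is fully concordant
  perf <- toy_dataset(time = 11 - (1:10), status = rep(1, 10), z = 1:10)
  expect_equal(concordance_index(perf, perf$prs)$c_statistic, 1)

  # independent score hovers near 0.5
  set.seed(20)
  big <- toy_dataset(runif(2000, 30, 70), rbinom(2000, 1, 0.5), rnorm(2000))
  expect_lt(abs(concordance_index(big, big$prs)$c_statistic - 0.5), 0.05)

  # cluster bootstrap is seeded and reproducible
  b1 <- concordance_index(ds, score, n_bootstrap = 30, seed = 4)
  b2 <- concordance_index(ds, score, n_bootstrap = 30, seed = 4)
  expect_equal(b1$bootstrap_se, b2$bootstrap_se)
  expect_gt(b1$bootstrap_se, 0)
})

test_that("left truncation with entry zero reduces to the retrospective fit", {
  sim <- simulate_retrospective_cohort(default_sim_config(
    n = 1500, seed = 23L, ascertainment_affected_fraction = NULL))
  co <- sim$cohort
  co$age_recruit <- 1e-6                 # effectively entry at birth
  fit_p <- fit_prospective_cox(co, "breast")
  ds <- build_analysis_dataset(co, "breast")
  fit_r <- fit_weighted_cox(ds)
  expect_equal(fit_p$coefficients["prs"], fit_r$coefficients["prs"],
               tolerance = 1e-8)
})

test_that("time-varying PRS fits recover constant and age-declining effects", {
  # constant effect: interaction term near zero
  sim <- simulate_retrospective_cohort(default_sim_config(
    n = 2500, seed = 33L, ascertainment_affected_fraction = NULL))
  ds <- build_analysis_dataset(sim$cohort, "breast")
  tv <- fit_time_varying_prs(ds, split = "events", age_center = 18)
  se1 <- sqrt(diag(tv$robust_covariance))["prs_x_age"]
  expect_lt(abs(tv$coefficients["prs_x_age"]), 3.5 * se1)

  # declining effect: beta(t) = beta0 + beta1 (t - 18), beta1 < 0
  sim2 <- simulate_retrospective_cohort(default_sim_config(
    n = 2500, seed = 34L, beta0 = log(1.8), ascertainment_affected_fraction = NULL,
    beta1 = -0.012, reference_age = 18))
  ds2 <- build_analysis_dataset(sim2$cohort, "breast")
  tv2 <- fit_time_varying_prs(ds2, split = "events", age_center = 18)
  se <- sqrt(diag(tv2$robust_covariance))
  expect_lt(abs(tv2$coefficients["prs"] - log(1.8)), 3 * se["prs"] + 0.02)
  expect_lt(abs(tv2$coefficients["prs_x_age"] + 0.012),
            3 * se["prs_x_age"] + 0.002)
  expect_lt(tv2$coefficients["prs_x_age"], 0)
})

test_that("family clustering inflates the robust variance under correlation", {
  set.seed(55)
  n_fam <- 400
  fam <- rep(seq_len(n_fam), each = 3)
  shared <- rnorm(n_fam)[fam]
  z <- sqrt(0.5) * shared + sqrt(0.5) * rnorm(length(fam))
  t_event <- rexp(length(fam), 0.02 * exp(0.4 * shared))  # outcome correlated in family
  cens <- runif(length(fam), 10, 60)
  ds <- toy_dataset(pmin(t_event, cens), as.integer(t_event <= cens), z,
                    cluster = fam)
  fit <- fit_weighted_cox(ds)
  expect_gt(fit$robust_covariance[1, 1], fit$naive_covariance[1, 1])
})
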