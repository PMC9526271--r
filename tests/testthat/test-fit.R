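# The longitudinal model: maximum likelihood with missing data, the
# known-covariance GLS step, and the primary-only comparison analysis.

test_that("primary-only analysis reproduces closed forms and printed-summary z", {
  # equal arm means -> beta = 0, z = 0
  d0 <- make_single_label_data(10, 30, 30, 5)
  e0 <- fit_primary_only(d0)
  expect_equal(e0$beta, 0)
  expect_equal(e0$z, 0)

  # shoulder-trial-like summaries: means 29.4 vs 32.7 with n = 90 per arm
  # and pooled SD 11.8 give a difference of 3.3 and z about 1.88
  d <- make_single_label_data(90, 29.4, 32.7, 11.8)
  e <- fit_primary_only(d)
  expect_equal(e$beta, 3.3, tolerance = 1e-12)
  expect_equal(e$z, 3.3 / (11.8 * sqrt(2 / 90)), tolerance = 1e-12)
  expect_equal(round(e$z, 2), 1.88)

  # information n/(2 sigma^2): sd 9, 20 per arm -> 0.123 to 3 dp
  di <- make_single_label_data(20, 30, 30, 9)
  expect_equal(round(fit_primary_only(di)$information, 3), 0.123)

  # variance closed form sigma^2 (1/n1 + 1/n0)
  expect_equal(e$variance, 11.8^2 * (2 / 90), tolerance = 1e-12)
})

test_that("orientation: lower-is-better scores flip the effect sign only", {
  d_hi <- make_single_label_data(10, 28, 31, 6, direction = "higher_better")
  e_hi <- fit_primary_only(d_hi)
  rec <- d_hi$records
  rec$value <- -rec$value
  d_lo <- longitudinal_dataset(rec, sched1("lower_better"))
  e_lo <- fit_primary_only(d_lo)
  expect_equal(e_lo$beta, e_hi$beta)
  expect_equal(e_lo$z, e_hi$z)
  expect_equal(e_lo$information, e_hi$information)

  d2 <- make_monotone_data(seed = 3)
  f_hi <- fit_mvn_longitudinal(d2)
  rec2 <- d2$records
  rec2$value <- -rec2$value
  f_lo <- fit_mvn_longitudinal(longitudinal_dataset(rec2, sched2("lower_better")))
  expect_equal(f_lo$estimate$beta, f_hi$estimate$beta, tolerance = 1e-9)
  expect_equal(f_lo$estimate$information, f_hi$estimate$information,
               tolerance = 1e-9)
})

test_that("with a single modelled label the full fit equals the primary-only fit", {
  # schedule with a late 12m label: only 6m is modelled
  sched <- outcome_schedule(c("6m", "12m"), c(183, 365), "6m")
  set.seed(8)
  n <- 60
  rec <- data.frame(
    participant_id = rep(sprintf("C%03d", 1:n), each = 2),
    arm = rep(rep(c("control", "test"), n / 2), each = 2),
    randomization_date = rep(as.Date("2013-01-01") + 1:n, each = 2),
    time_label = rep(c("6m", "12m"), n),
    assessment_date = rep(as.Date("2013-01-01") + 1:n, each = 2) + c(183, 365),
    value = rnorm(2 * n, 30, 9))
  d <- longitudinal_dataset(rec, sched)
  full <- fit_mvn_longitudinal(d)$estimate
  prim <- fit_primary_only(d)
  expect_equal(full$beta, prim$beta, tolerance = 1e-9)
  expect_equal(full$z, prim$z, tolerance = 1e-9)
  expect_equal(full$information, prim$information, tolerance = 1e-9)
})

test_that("known-covariance GLS matches a dense brute-force oracle", {
  d <- make_monotone_data(n_per_arm = 12, n_complete = 7, seed = 9)
  cm <- covariance_model(c(`3m` = 8, `6m` = 10), 0.6)
  est <- estimate_with_fixed_cov(d, cm)
  orc <- gls_oracle(d, cov_matrix(cm), c("3m", "6m"))
  expect_equal(est$beta, orc$beta, tolerance = 1e-10)
  expect_equal(est$variance, orc$var_beta, tolerance = 1e-10)
})

test_that("zero correlation makes early data irrelevant to the GLS estimate", {
  d <- make_monotone_data(n_per_arm = 20, n_complete = 12, seed = 10)
  cm0 <- covariance_model(c(`3m` = 8, `6m` = 10), 0)
  est <- estimate_with_fixed_cov(d, cm0)
  n_t <- 12  # per-arm complete
  expect_equal(est$variance, 10^2 * (2 / n_t), tolerance = 1e-10)
  # beta equals the raw primary-label mean difference
  prim <- d$records[d$records$time_label == "6m", ]
  raw <- mean(prim$value[prim$arm == "test"]) -
    mean(prim$value[prim$arm == "control"])
  expect_equal(est$beta, raw, tolerance = 1e-10)
})

test_that("with complete data the full estimate equals the primary-only difference", {
  d <- make_monotone_data(n_per_arm = 25, n_complete = 25, seed = 11)
  cm <- covariance_model(c(`3m` = 8, `6m` = 10), 0.6)
  gls <- estimate_with_fixed_cov(d, cm)
  prim <- fit_primary_only(d)
  expect_equal(gls$beta, prim$beta, tolerance = 1e-9)
  ml <- fit_mvn_longitudinal(d, tol = 1e-12)
  expect_equal(ml$estimate$beta, prim$beta, tolerance = 1e-7)
})

test_that("monotone-missingness ML matches the closed-form factorization oracle", {
  for (seed in c(21, 22, 23)) {
    d <- make_monotone_data(n_per_arm = 40, n_complete = 24, seed = seed)
    fit <- fit_mvn_longitudinal(d, tol = 1e-13)
    expect_equal(fit$estimate$beta, monotone_ml_oracle(d), tolerance = 1e-6)
  }
})

test_that("information identities and the early-outcome information gain hold", {
  cm <- covariance_model(c(`3m` = 8, `6m` = 10), 0.6)
  for (seed in 31:35) {
    d <- make_monotone_data(n_per_arm = 30, n_complete = 18, seed = seed)
    full <- estimate_with_fixed_cov(d, cm)
    prim <- fit_primary_only(d)
    ml <- fit_mvn_longitudinal(d)
    for (e in list(full, prim, ml$estimate)) {
      expect_equal(e$z^2, e$beta^2 * e$information, tolerance = 1e-12)
      expect_equal(e$information, 1 / e$variance, tolerance = 1e-12)
    }
    # borrowing from correlated early outcomes cannot lose information
    prim_fixed_var <- cov_matrix(cm)[2, 2] * (2 / 18)
    expect_lte(full$variance, prim_fixed_var + 1e-12)
  }
  # equality when no early-only participants exist
  d_eq <- make_monotone_data(n_per_arm = 20, n_complete = 20, seed = 36)
  full_eq <- estimate_with_fixed_cov(d_eq, cm)
  expect_equal(full_eq$variance, cov_matrix(cm)[2, 2] * (2 / 20),
               tolerance = 1e-10)
})

test_that("maximum likelihood recovers the generating parameters", {
  sched <- sched2()
  cm <- covariance_model(c(`3m` = 8, `6m` = 10), 0.65)
  tm <- trial_template("recov", 4000, sched,
                       data.frame(duration_days = 400, rate_per_day = 11),
                       rbind(control = c(20, 30), test = c(22, 33)),
                       cm, dropout_hazard = 0.1,
                       intermittent_missing_rate = 0.05)
  d <- generate_trial(tm, 777)
  fit <- fit_mvn_longitudinal(d)
  # mean recovery within 3 Monte-Carlo SEs
  npl <- n_per_label(d, by_arm = TRUE)
  for (a in c("control", "test")) for (l in c("3m", "6m")) {
    se <- cm$sigmas[l] / sqrt(npl[l, a])
    expect_lt(abs(fit$mu[a, l] - tm$arm_means[a, l]), 3 * se)
  }
  expect_lt(abs(fit$cov$correlations["3m", "6m"] - 0.65), 0.05)
  expect_lt(abs(fit$cov$sigmas["6m"] - 10), 0.5)
})

test_that("degenerate inputs raise the documented errors and warnings", {
  d <- make_single_label_data(4, 30, 32, 5)
  rec <- d$records[d$records$arm == "control", ]
  rec <- rbind(rec, transform(d$records[d$records$arm == "test", ][1, ],
                              value = 31))
  dd <- longitudinal_dataset(rec, sched1())
  expect_error(fit_primary_only(dd), "information undefined")
  expect_error(fit_mvn_longitudinal(dd), "information undefined")

  # an early label with < 2 observations is dropped with a warning
  d2 <- make_monotone_data(n_per_arm = 10, n_complete = 8, seed = 50)
  rec2 <- d2$records
  keep <- rec2$time_label == "6m" | rec2$participant_id == "M001"
  d2thin <- longitudinal_dataset(rec2[keep, ], sched2())
  expect_warning(fit_mvn_longitudinal(d2thin), "fewer than 2 observations")

  # covariance model must cover the modelled labels
  expect_error(
    estimate_with_fixed_cov(d2, covariance_model(c(`6m` = 10), matrix(1, 1, 1))),
    "does not cover")
})
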