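# The synthetic dated-trial generator and the seven preset configurations.

test_that("no dropout and no intermittent holes gives complete follow-up", {
  sched <- sched2()
  tm <- trial_template("complete", 50, sched,
                       data.frame(duration_days = 200, rate_per_day = 0.5),
                       rbind(control = c(20, 30), test = c(20, 30)),
                       covariance_model(c(`3m` = 8, `6m` = 10), 0.5))
  d <- generate_trial(tm, 1)
  expect_equal(unname(n_per_label(d)), c(50L, 50L))
  # permuted blocks of 2 give near-exact 1:1 allocation
  expect_lte(abs(sum(d$participants$arm == "test") - 25L), 1L)
})

test_that("generated outcomes reproduce the template covariance", {
  sched <- sched2()
  tm <- trial_template("big", 10000, sched,
                       data.frame(duration_days = 1000, rate_per_day = 11),
                       rbind(control = c(20, 30), test = c(20, 30)),
                       covariance_model(c(`3m` = 8, `6m` = 10), 0.7),
                       dropout_hazard = c(0.08, 0),
                       intermittent_missing_rate = 0.05)
  d <- generate_trial(tm, 2)
  w <- gsreplay:::.wide_data(d)
  cc <- complete.cases(w$Y)
  expect_lt(abs(cor(w$Y[cc, 1], w$Y[cc, 2]) - 0.7), 0.02)
  expect_lt(abs(sd(w$Y[, 2], na.rm = TRUE) - 10), 0.3)
  # primary-label missingness converges to the dropout + intermittent mix
  p_miss <- 1 - n_per_label(d)["6m"] / 10000
  expect_lt(abs(p_miss - (1 - 0.92 * 0.95)), 0.015)
})

test_that("identical seeds give byte-identical output; different seeds differ", {
  tm <- seven_trial_presets()$WAT
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(generate_trial(tm, 123), f1)
  write_trial_csv(generate_trial(tm, 123), f2)
  write_trial_csv(generate_trial(tm, 124), f3)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("the seven presets match their published configurations", {
  pres <- seven_trial_presets()
  expect_named(pres, c("WAT", "DRAFFT", "WOLLF", "FASHION", "CSAW",
                       "FIXDT", "TOPKAT"))
  sizes <- vapply(pres, function(t) t$n_total, 1L)
  expect_equal(unname(sizes), c(126L, 461L, 460L, 348L, 210L, 321L, 528L))

  wat <- generate_trial(pres$WAT, 5)
  expect_equal(nrow(wat$participants), 126L)
  expect_equal(wat$schedule$labels, c("6w", "3m", "6m", "12m"))
  expect_equal(wat$schedule$primary_label, "12m")

  expect_equal(pres$DRAFFT$schedule$labels, c("3m", "6m", "12m"))
  expect_equal(pres$DRAFFT$schedule$primary_label, "12m")
  expect_equal(pres$DRAFFT$schedule$direction, "lower_better")

  # the 6m-primary trials model only occasions up to 6m
  expect_equal(modelled_labels(pres$CSAW$schedule), "6m")
  expect_equal(modelled_labels(pres$FIXDT$schedule), c("3m", "6m"))

  # every preset covariance is positive definite
  for (t in pres) {
    ev <- eigen(cov_matrix(t$cov), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }

  # an alternative-effect template shifts the oriented contrast positively
  alt <- seven_trial_presets(effect = 5)$WOLLF
  expect_equal(unname(alt$arm_means["test", ] - alt$arm_means["control", ]),
               rep(-5, 4))  # lower-is-better scale: test arm scores lower
})

test_that("infeasible recruitment is rejected", {
  expect_error(
    trial_template("none", 10, sched1(),
                   data.frame(duration_days = 100, rate_per_day = 0),
                   rbind(control = 30, test = 30),
                   covariance_model(c(`6m` = 9), matrix(1, 1, 1))),
    "accrual is zero")
})
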