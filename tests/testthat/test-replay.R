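# Calendar-time replay: windows, snapshots, triggering, stopping,
# overrunning.

test_that("snapshots respect calendar time and grow monotonically", {
  d <- generate_trial(seven_trial_presets()$WAT, 4)
  first <- min(d$participants$randomization_date)
  empty <- snapshot(d, first - 1)
  expect_equal(nrow(empty$participants), 0L)
  expect_equal(nrow(empty$records), 0L)

  full <- snapshot(d, max(d$records$assessment_date))
  expect_equal(full$records, d$records)
  expect_equal(full$participants, d$participants)

  set.seed(99)
  span <- as.numeric(max(d$records$assessment_date) - first)
  for (i in 1:100) {
    t1 <- first + sample.int(span, 1)
    t2 <- first + sample.int(span, 1)
    lo <- min(t1, t2); hi <- max(t1, t2)
    expect_lte(nrow(snapshot(d, lo)$records), nrow(snapshot(d, hi)$records))
  }
})

test_that("the window of opportunity opens with data and closes with recruitment", {
  pres <- seven_trial_presets()
  # five-year primary follow-up exceeds the recruitment span: empty window
  w_topkat <- window_of_opportunity(generate_trial(pres$TOPKAT, 7))
  expect_true(w_topkat$empty)

  # a long-recruitment four-occasion trial: window spans > 12 months
  w_wollf <- window_of_opportunity(generate_trial(pres$WOLLF, 7))
  expect_false(w_wollf$empty)
  expect_gt(as.numeric(w_wollf$end - w_wollf$start), 365)

  # near-instant follow-up with slow recruitment: window ~ recruitment period
  sched0 <- outcome_schedule("d1", 1, "d1")
  tm <- trial_template("instant", 80, sched0,
                       data.frame(duration_days = 800, rate_per_day = 0.11),
                       rbind(control = 30, test = 30),
                       covariance_model(c(d1 = 9), matrix(1, 1, 1)),
                       assessment_jitter_sd_days = 0)
  d <- generate_trial(tm, 21)
  w <- window_of_opportunity(d)
  expect_false(w$empty)
  expect_lt(as.numeric(w$start - min(d$participants$randomization_date)), 120)
  expect_equal(w$end, max(d$participants$randomization_date))
})

test_that("sentinel boundaries never stop and leave only the final analysis", {
  d <- generate_trial(oc_null_template(), 31)
  b <- oc_null_bounds("a", 1)
  wide <- b
  wide$lower <- -20
  wide$upper <- 20
  r <- replay(d, wide, cov = oc_null_template()$cov)
  expect_false(r$stopped)
  expect_equal(length(r$interims), 1L)
  expect_equal(r$interims[[1]]$decision, "continue")
  expect_false(is.null(r$final))
  expect_null(r$overrun)
})

test_that("interims trigger at the first monitoring date reaching I*", {
  d <- generate_trial(oc_null_template(), 17)
  tm <- oc_null_template()
  b <- oc_null_bounds("b", 2)
  r <- replay(d, b, cov = tm$cov)
  expect_gte(length(r$interims), 1L)
  log <- r$log
  for (it in r$interims) {
    expect_gte(it$info_observed, it$info_planned)
    before <- log$info[log$date < it$date & !is.na(log$info)]
    if (it$k == 1L) expect_true(all(before < it$info_planned))
  }
  # monitoring log is biweekly inside the window
  expect_equal(unique(diff(as.numeric(log$date))), 14)
  # the recorded interim estimate is reproduced exactly by re-fitting the
  # trigger-date snapshot
  it <- r$interims[[1]]
  refit <- estimate_with_fixed_cov(snapshot(d, it$date), tm$cov)
  expect_identical(refit$beta, it$est_full$beta)
  expect_identical(refit$information, it$est_full$information)
})

test_that("decisions never depend on data dated after the stop", {
  tm <- oc_null_template()
  b <- oc_null_bounds("d", 3)
  found <- FALSE
  for (seed in 101:140) {
    d <- generate_trial(tm, seed)
    r <- replay(d, b, cov = tm$cov, overrun = FALSE, log = FALSE)
    if (!r$stopped) next
    found <- TRUE
    rec <- d$records
    after <- which(rec$assessment_date > r$stop_date)
    if (!length(after)) next
    rec$value[after] <- rec$value[after] + 50
    d2 <- longitudinal_dataset(rec, d$schedule, d$participants)
    r2 <- replay(d2, b, cov = tm$cov, overrun = FALSE, log = FALSE)
    expect_identical(r2$stop_reason, r$stop_reason)
    expect_identical(r2$stop_date, r$stop_date)
    expect_identical(length(r2$interims), length(r$interims))
    break
  }
  expect_true(found)
})

test_that("a null trial under the most aggressive futility setting usually stops", {
  oc <- simulate_oc(oc_null_template(), oc_null_bounds("d", 3),
                    n_reps = 500, seed = 2024)
  expect_gte(oc$futility_total, 0.90)
})

test_that("overrunning analyses extend, and qualitatively agree with, interim fits", {
  # a harm-leaning test arm, as in the trial this template emulates, so
  # futility stops are frequent and the true effect is away from zero
  tm <- seven_trial_presets(effect = -3)$WOLLF
  b <- wollf_like_bounds("b")
  agree <- 0L
  stops <- 0L
  for (seed in 301:340) {
    d <- generate_trial(tm, seed)
    r <- replay(d, b, cov = tm$cov, log = FALSE)
    if (!r$stopped || r$stop_reason != "stop_futility") next
    stops <- stops + 1L
    it <- r$interims[[length(r$interims)]]
    # overrun uses a superset of the interim data, label by label
    expect_true(all(r$overrun$n_per_label >= it$est_full$n_per_label))
    if (sign(r$overrun$beta) == sign(it$est_full$beta) ||
        abs(it$est_full$beta) < 1e-8)
      agree <- agree + 1L
  }
  expect_gte(stops, 10L)
  expect_gt(agree / stops, 0.8)

  # stopping after the last randomization makes overrun = end-of-trial fit
  d <- generate_trial(tm, 999)
  fake <- structure(list(stopped = TRUE,
                         stop_date = max(d$records$assessment_date),
                         cov_mode = tm$cov),
                    class = "gs_replay")
  ov <- overrun_analysis(d, fake)
  full <- estimate_with_fixed_cov(d, tm$cov)
  expect_equal(ov$beta, full$beta, tolerance = 1e-12)

  not_stopped <- structure(list(stopped = FALSE), class = "gs_replay")
  expect_error(overrun_analysis(d, not_stopped), "stopped")
})

test_that("maximum-likelihood replay mirrors the known-covariance path", {
  pres <- seven_trial_presets()
  d <- generate_trial(pres$FIXDT, 61)
  labels <- modelled_labels(pres$FIXDT$schedule)
  acc <- planned_accrual(matrix(c(60, 30, 120, 70), 2, 2, byrow = TRUE),
                         c(290, 270), labels = labels)
  istar <- expected_information(
    acc, covariance_model(stats::setNames(c(20, 20), labels), 0.5))
  b <- compute_boundaries(make_spending_plan("c", 2), as.numeric(istar))
  r <- replay(d, b)  # ML at every monitoring date
  s <- summary(r)
  expect_true(all(c("beta", "z", "info", "beta0", "z0", "info0") %in% names(s)))
  expect_true(all(diff(as.numeric(s$date)) >= 0))
  # at every conducted analysis borrowing cannot have lost information
  expect_true(all(s$info >= s$info0 - 1e-9))
  if (r$stopped) {
    it <- r$interims[[length(r$interims)]]
    refit <- fit_mvn_longitudinal(snapshot(d, it$date))
    expect_equal(refit$estimate$beta, it$est_full$beta, tolerance = 1e-9)
  } else {
    expect_false(is.null(r$final))
  }
})
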