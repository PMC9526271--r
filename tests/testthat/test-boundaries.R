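# Error-spending boundary construction and exit probabilities.

test_that("spending presets encode the four futility settings", {
  p <- make_spending_plan("a", 1)
  expect_equal(p$cum_lower, 0.160)
  expect_equal(p$cum_upper, 0.005)
  expect_equal(c(p$final_lower, p$final_upper), c(0.975, 0.025))
  p3 <- make_spending_plan("d", 3)
  expect_equal(p3$cum_lower, c(0.320, 0.640, 0.960))
  expect_equal(p3$cum_upper, c(0.001, 0.005, 0.010))
  expect_error(make_spending_plan("a", 4), "1, 2 or 3")
  expect_error(make_spending_plan("a", 0), "1, 2 or 3")
  expect_error(spending_plan(c(0.2, 0.1), c(0.001, 0.01)), "increasing")
})

test_that("first-look boundaries are the marginal normal quantiles", {
  b <- compute_boundaries(make_spending_plan("a", 1), c(0.123, 0.525))
  expect_equal(b$lower[1], qnorm(0.160), tolerance = 1e-10)
  expect_equal(b$upper[1], qnorm(0.995), tolerance = 1e-10)
  expect_lt(b$lower[1], b$upper[1])
})

test_that("a design with no interims reduces to the fixed-sample critical value", {
  b <- compute_boundaries(spending_plan(numeric(0), numeric(0)), 1)
  expect_equal(b$final_crit, qnorm(0.975), tolerance = 1e-12)
})

test_that("under the null the solved boundaries reproduce the spending plan", {
  for (s in c("a", "b", "c", "d")) for (K in 1:3) {
    plan <- make_spending_plan(s, K)
    il <- seq(0.25, 1, length.out = K + 1)
    b <- compute_boundaries(plan, il)
    ep <- exit_probabilities(b, drift = 0)
    expect_equal(cumsum(ep$p_lower)[seq_len(K)], plan$cum_lower,
                 tolerance = 1e-8)
    expect_equal(cumsum(ep$p_upper)[seq_len(K)], plan$cum_upper,
                 tolerance = 1e-8)
    expect_equal(attr(ep, "total_upper"), 0.025, tolerance = 1e-8)
    expect_equal(attr(ep, "total_lower") + attr(ep, "total_upper"), 1,
                 tolerance = 1e-6)
  }
})

test_that("futility boundaries rise monotonically from setting a to d", {
  for (K in 1:3) {
    il <- seq(0.25, 1, length.out = K + 1)
    ls <- sapply(c("a", "b", "c", "d"), function(s)
      compute_boundaries(make_spending_plan(s, K), il)$lower)
    ls <- matrix(ls, nrow = K)
    expect_true(all(apply(ls, 1, diff) >= -1e-12))
  }
})

test_that("grid exit probabilities agree with a Monte-Carlo path oracle", {
  b <- compute_boundaries(make_spending_plan("b", 3), c(0.2, 0.4, 0.6, 1))
  for (drift in c(0, 1.5)) {
    mc <- mc_exit_probs(b$lower, b$upper, b$final_crit, b$info_levels,
                        drift = drift, n = 2e5, seed = 123)
    ep <- exit_probabilities(b, drift = drift)
    se <- sqrt(pmax(mc$p_lower * (1 - mc$p_lower), 0.25e-4) / 2e5)
    expect_true(all(abs(ep$p_lower - mc$p_lower) <= 3 * se + 1e-9))
    se_u <- sqrt(pmax(mc$p_upper * (1 - mc$p_upper), 0.25e-4) / 2e5)
    expect_true(all(abs(ep$p_upper - mc$p_upper) <= 3 * se_u + 1e-9))
  }
})

test_that("a strong positive drift exits for efficacy almost surely", {
  b <- compute_boundaries(make_spending_plan("c", 2), c(0.3, 0.6, 1))
  ep <- exit_probabilities(b, drift = 20)
  expect_equal(attr(ep, "total_upper"), 1, tolerance = 1e-6)
})

test_that("invalid plans and information sequences are rejected", {
  plan <- make_spending_plan("b", 2)
  expect_error(compute_boundaries(plan, c(0.3, 0.6)), "length")
  expect_error(compute_boundaries(plan, c(0.6, 0.3, 1)), "increasing")
  # total spending at a look must stay below 1; this is what would
  # otherwise make the futility and efficacy boundaries overlap
  expect_error(spending_plan(c(0.50, 0.98), c(0.010, 0.030)), "below 1")
})
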