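# Shared fixtures and independent oracles, built in code at test time.

# -- simple schedules ---------------------------------------------------------

sched1 <- function(direction = "higher_better")
  outcome_schedule("6m", 183, "6m", direction)

sched2 <- function(direction = "higher_better")
  outcome_schedule(c("3m", "6m"), c(91, 183), "6m", direction)

# -- hand-built datasets ------------------------------------------------------

# Complete single-label dataset with exact arm means and exact pooled ML SD
# (half the values at m + s, half at m - s in each arm).
make_single_label_data <- function(n_per_arm, mean_control, mean_test, sd,
                                   direction = "higher_better") {
  stopifnot(n_per_arm %% 2 == 0)
  vals <- function(m) rep(c(m + sd, m - sd), n_per_arm / 2)
  n <- 2 * n_per_arm
  data.frame(
    participant_id = sprintf("S%03d", seq_len(n)),
    arm = rep(c("control", "test"), each = n_per_arm),
    randomization_date = as.Date("2015-01-01") + seq_len(n),
    time_label = "6m",
    assessment_date = as.Date("2015-01-01") + seq_len(n) + 183,
    value = c(vals(mean_control), vals(mean_test))) |>
    longitudinal_dataset(sched1(direction))
}

# Two-label dataset with monotone missingness: everyone has 3m, the first
# n_complete per arm also have 6m. Values drawn from a known MVN.
make_monotone_data <- function(n_per_arm = 40, n_complete = 25,
                               mu_control = c(20, 30), mu_test = c(22, 34),
                               sigma = c(8, 10), rho = 0.6, seed = 42,
                               direction = "higher_better") {
  set.seed(seed)
  S <- covariance_model(c(`3m` = sigma[1], `6m` = sigma[2]), rho)
  n <- 2 * n_per_arm
  arm <- rep(c("control", "test"), each = n_per_arm)
  Y <- MASS::mvrnorm(n, c(0, 0), cov_matrix(S)) +
    rbind(mu_control, mu_test)[ifelse(arm == "test", 2, 1), ]
  has6m <- rep(seq_len(n_per_arm) <= n_complete, 2)
  rows <- list()
  for (i in seq_len(n)) {
    labs <- if (has6m[i]) c("3m", "6m") else "3m"
    rows[[i]] <- data.frame(
      participant_id = sprintf("M%03d", i), arm = arm[i],
      randomization_date = as.Date("2015-01-01") + i,
      time_label = labs,
      assessment_date = as.Date("2015-01-01") + i + c(91, 183)[seq_along(labs)],
      value = Y[i, seq_along(labs)])
  }
  longitudinal_dataset(do.call(rbind, rows), sched2(direction))
}

# -- independent oracles ------------------------------------------------------

# Brute-force GLS with known Sigma: one dense block-diagonal system over the
# stacked observed values, solved directly (independent of the package's
# pattern-wise accumulation).
gls_oracle <- function(data, Sigma, labels) {
  part <- data$participants
  rec <- data$records[data$records$time_label %in% labels, , drop = FALSE]
  ids <- part$participant_id
  y <- numeric(0)
  Xrows <- list()
  Vblocks <- list()
  p <- 2 * length(labels)  # control means then test means
  for (i in seq_along(ids)) {
    ri <- rec[rec$participant_id == ids[i], , drop = FALSE]
    if (!nrow(ri)) next
    O <- match(ri$time_label, labels)
    y <- c(y, ri$value)
    X <- matrix(0, length(O), p)
    off <- if (part$arm[i] == "test") length(labels) else 0
    X[cbind(seq_along(O), off + O)] <- 1
    Xrows[[length(Xrows) + 1L]] <- X
    Vblocks[[length(Vblocks) + 1L]] <- Sigma[O, O, drop = FALSE]
  }
  X <- do.call(rbind, Xrows)
  V <- matrix(0, length(y), length(y))
  at <- 0
  for (B in Vblocks) {
    idx <- at + seq_len(nrow(B))
    V[idx, idx] <- B
    at <- at + nrow(B)
  }
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  C <- solve(XtVi %*% X)
  est <- as.numeric(C %*% XtVi %*% y)
  tL <- length(labels)
  list(mu = est, beta = est[2 * tL] - est[tL],
       var_beta = C[tL, tL] + C[2 * tL, 2 * tL])
}

# Closed-form ML for the monotone two-label model with common Sigma and
# per-arm means, via the marginal/conditional regression factorization.
monotone_ml_oracle <- function(data) {
  labels <- c("3m", "6m")
  part <- data$participants
  rec <- data$records
  w <- reshape(rec[c("participant_id", "time_label", "value")],
               idvar = "participant_id", timevar = "time_label",
               direction = "wide")
  w$arm <- part$arm[match(w$participant_id, part$participant_id)]
  y1 <- w$value.3m
  y2 <- w$value.6m
  mu1 <- tapply(y1, w$arm, mean)
  cc <- !is.na(y2)
  fit <- lm(y2[cc] ~ 0 + factor(w$arm[cc]) + y1[cc])
  co <- coef(fit)
  b <- co[3]
  alpha <- co[1:2]  # control, test intercepts (factor level order)
  mu2 <- alpha + b * mu1[c("control", "test")]
  unname(mu2["test"] - mu2["control"])
}

# Monte-Carlo oracle for sequential exit probabilities under the canonical
# joint law (independent score increments).
mc_exit_probs <- function(lower, upper, final_crit, info, drift = 0,
                          n = 1e6, seed = 1) {
  set.seed(seed)
  K <- length(lower)
  dI <- diff(c(0, info))
  S <- numeric(n)
  alive <- rep(TRUE, n)
  p_lower <- p_upper <- numeric(K + 1)
  for (k in seq_len(K)) {
    S <- S + rnorm(n, drift * dI[k], sqrt(dI[k]))
    Z <- S / sqrt(info[k])
    low <- alive & Z <= lower[k]
    up <- alive & Z >= upper[k]
    p_lower[k] <- mean(low)
    p_upper[k] <- mean(up)
    alive <- alive & !low & !up
  }
  S <- S + rnorm(n, drift * dI[K + 1], sqrt(dI[K + 1]))
  Z <- S / sqrt(info[K + 1])
  p_upper[K + 1] <- mean(alive & Z >= final_crit)
  p_lower[K + 1] <- mean(alive & Z < final_crit)
  list(p_lower = p_lower, p_upper = p_upper)
}

# -- templates and designs for replay simulations -----------------------------

# Clean null single-label template: complete follow-up, known SD, used for
# operating-characteristic checks where the spending plan should be
# reproduced by the full generate -> replay pipeline.
oc_null_template <- function(n = 210, sigma = 9) {
  trial_template("oc_null", n, sched1(),
                 data.frame(duration_days = 1000, rate_per_day = n / 1000 * 1.02),
                 rbind(control = 30, test = 30),
                 covariance_model(c(`6m` = sigma), matrix(1, 1, 1)),
                 dropout_hazard = 0, intermittent_missing_rate = 0)
}

oc_null_bounds <- function(setting, n_interims, n = 210, sigma = 9) {
  counts <- c(40, 80, 120)[seq_len(n_interims)]
  acc <- planned_accrual(counts, n, labels = "6m")
  istar <- expected_information(acc, covariance_model(c(`6m` = sigma), matrix(1, 1, 1)))
  compute_boundaries(make_spending_plan(setting, n_interims),
                     as.numeric(istar))
}

# WOLLF-like design: three interims at the published planned information
# levels for that trial (0.025, 0.050, 0.075; final 0.165).
wollf_like_bounds <- function(setting = "b") {
  compute_boundaries(make_spending_plan(setting, 3),
                     c(0.025, 0.050, 0.075, 0.165))
}
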