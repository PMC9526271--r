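# Synthetic dated two-arm PROM trials with the statistical structure the
# analysis assumes: piecewise-constant Poisson recruitment, permuted-block
# 1:1 allocation, multivariate-normal outcomes with an unstructured
# covariance, jittered assessment dates, monotone dropout and intermittent
# missingness. Presets emulate the published configurations (sample sizes,
# schedules, protocol standard deviations, recruitment spans) of seven
# recent surgical RCTs; they are synthetic stand-ins, not the trials' data.

#' Template for a synthetic two-arm longitudinal trial
#'
#' @param name template name.
#' @param n_total total number randomized (1:1 by permuted blocks of 2).
#' @param schedule an [outcome_schedule()] (may include late labels).
#' @param recruitment data frame with columns `duration_days` and
#'   `rate_per_day`: piecewise-constant Poisson recruitment intensities
#'   (supports slow-pilot-then-ramp profiles); the final positive rate is
#'   extended if needed to reach `n_total`.
#' @param arm_means 2-by-L matrix (rows `control`, `test`) of mean outcome
#'   trajectories over all schedule labels, in PROM units.
#' @param cov a [covariance_model()] over all schedule labels: the true
#'   per-occasion SDs and between-occasion correlations.
#' @param dropout_hazard per-label probability of permanently leaving
#'   follow-up *after* that label's assessment (monotone dropout); scalar
#'   or length-L vector, entries in `[0, 1]`.
#' @param intermittent_missing_rate probability that any individual
#'   remaining assessment is missing (non-monotone MCAR holes).
#' @param assessment_jitter_sd_days SD (days) of Gaussian jitter around the
#'   nominal assessment offsets.
#' @param start_date calendar origin of recruitment (arbitrary; only
#'   relative dates matter).
#' @return An object of class `trial_template`.
#' @export
trial_template <- function(name, n_total, schedule, recruitment, arm_means,
                           cov, dropout_hazard = 0,
                           intermittent_missing_rate = 0,
                           assessment_jitter_sd_days = 3,
                           start_date = as.Date("2010-01-01")) {
  stopifnot(inherits(schedule, "outcome_schedule"),
            inherits(cov, "covariance_model"))
  n_total <- as.integer(n_total)
  if (n_total <= 0L) stop("n_total must be positive")
  recruitment <- as.data.frame(recruitment)
  if (!all(c("duration_days", "rate_per_day") %in% names(recruitment)))
    stop("recruitment needs columns duration_days and rate_per_day")
  if (any(recruitment$rate_per_day < 0) || any(recruitment$duration_days <= 0))
    stop("recruitment rates must be >= 0 and durations positive")
  if (all(recruitment$rate_per_day == 0))
    stop("expected accrual is zero: all recruitment rates are 0")
  L <- length(schedule$labels)
  arm_means <- as.matrix(arm_means)
  if (!all(dim(arm_means) == c(2L, L)))
    stop("arm_means must be a 2-by-", L, " matrix (control, test)")
  dimnames(arm_means) <- list(c("control", "test"), schedule$labels)
  if (!setequal(names(cov$sigmas), schedule$labels))
    stop("covariance model labels must match the schedule labels")
  dropout_hazard <- rep_len(as.numeric(dropout_hazard), L)
  if (any(dropout_hazard < 0 | dropout_hazard > 1) ||
      intermittent_missing_rate < 0 || intermittent_missing_rate > 1)
    stop("missingness probabilities must lie in [0, 1]")
  structure(
    list(name = name, n_total = n_total, schedule = schedule,
         recruitment = recruitment, arm_means = arm_means, cov = cov,
         dropout_hazard = dropout_hazard,
         intermittent_missing_rate = intermittent_missing_rate,
         assessment_jitter_sd_days = assessment_jitter_sd_days,
         start_date = as.Date(start_date)),
    class = "trial_template")
}

#' @export
print.trial_template <- function(x, ...) {
  cat("Trial template '", x$name, "': N = ", x$n_total, ", labels ",
      paste(x$schedule$labels, collapse = "/"), " (primary ",
      x$schedule$primary_label, ")\n", sep = "")
  invisible(x)
}

# Poisson-process arrival days under piecewise-constant rates, extended at
# the last positive rate until n arrivals exist.
.recruitment_days <- function(recruitment, n) {
  days <- numeric(0)
  t0 <- 0
  for (i in seq_len(nrow(recruitment))) {
    dur <- recruitment$duration_days[i]
    rate <- recruitment$rate_per_day[i]
    if (rate > 0) {
      m <- stats::rpois(1, rate * dur)
      if (m > 0) days <- c(days, t0 + sort(stats::runif(m, 0, dur)))
    }
    t0 <- t0 + dur
  }
  rate <- rev(recruitment$rate_per_day[recruitment$rate_per_day > 0])[1]
  while (length(days) < n) {
    m <- stats::rpois(1, rate * 365)
    if (m > 0) days <- c(days, t0 + sort(stats::runif(m, 0, 365)))
    t0 <- t0 + 365
  }
  days[seq_len(n)]
}

#' Generate a synthetic dated trial from a template
#'
#' Reproducible given the seed: randomization dates from the recruitment
#' process truncated at `n_total`; permuted-block 1:1 assignment; one
#' multivariate-normal outcome vector per participant; assessment dates at
#' the nominal offsets plus Gaussian jitter; monotone dropout followed by
#' intermittent MCAR deletion. Missing assessments are simply absent rows.
#'
#' @param template a [trial_template()].
#' @param seed integer RNG seed.
#' @return A [longitudinal_dataset()] (the register contains all
#'   randomized participants, including any without observed assessments).
#' @export
generate_trial <- function(template, seed) {
  stopifnot(inherits(template, "trial_template"))
  set.seed(as.integer(seed))
  n <- template$n_total
  sched <- template$schedule
  L <- length(sched$labels)

  days <- .recruitment_days(template$recruitment, n)
  rand_date <- template$start_date + floor(days)
  arm <- character(n)
  nb <- ceiling(n / 2)
  blocks <- replicate(nb, sample(c("control", "test")))
  arm <- as.vector(blocks)[seq_len(n)]

  S <- cov_matrix(template$cov, sched$labels)
  Y <- MASS::mvrnorm(n, mu = rep(0, L), Sigma = S) +
    template$arm_means[ifelse(arm == "test", 2L, 1L), , drop = FALSE]

  jit <- matrix(stats::rnorm(n * L, 0, template$assessment_jitter_sd_days),
                n, L)
  off <- matrix(sched$offsets_days, n, L, byrow = TRUE)
  adates <- pmax(round(off + jit), 1)

  keep <- matrix(TRUE, n, L)
  drop_u <- matrix(stats::runif(n * L), n, L)
  dropped <- rep(FALSE, n)
  for (j in seq_len(L)) {
    keep[, j] <- !dropped
    dropped <- dropped | (drop_u[, j] < template$dropout_hazard[j])
  }
  if (template$intermittent_missing_rate > 0)
    keep <- keep & (matrix(stats::runif(n * L), n, L) >=
                      template$intermittent_missing_rate)

  idx <- which(keep, arr.ind = TRUE)
  records <- data.frame(
    participant_id = sprintf("P%04d", idx[, 1]),
    arm = arm[idx[, 1]],
    randomization_date = rand_date[idx[, 1]],
    time_label = sched$labels[idx[, 2]],
    assessment_date = rand_date[idx[, 1]] + adates[cbind(idx[, 1], idx[, 2])],
    value = Y[idx])
  participants <- data.frame(participant_id = sprintf("P%04d", seq_len(n)),
                             arm = arm, randomization_date = rand_date)
  ord <- order(records$randomization_date, records$participant_id,
               match(records$time_label, sched$labels))
  longitudinal_dataset(records[ord, , drop = FALSE], sched, participants)
}

# Correlation matrix from the target early-vs-primary correlations: pairs
# of early occasions get the larger of the two primary correlations,
# capped below 1, then the matrix is repaired to positive definiteness.
.corr_from_primary <- function(rho_primary) {
  L <- length(rho_primary) + 1L
  R <- diag(1, L)
  R[L, -L] <- R[-L, L] <- rho_primary
  if (L > 2L) {
    for (j in 1:(L - 2)) for (k in (j + 1):(L - 1)) {
      R[j, k] <- R[k, j] <- min(0.95, max(rho_primary[j], rho_primary[k]) + 0.05)
    }
  }
  repair_correlation(R, eps = 0.01)
}

#' Synthetic templates emulating seven surgical RCT configurations
#'
#' Returns templates matching the published sample sizes, outcome schedules,
#' score orientations, recruitment spans and protocol (design-stage)
#' standard deviations of seven recent UK trauma-and-orthopaedics RCTs:
#' WAT (N=126, OHS at 6w/3m/6m/12m), DRAFFT (N=461, PRWE at 3m/6m/12m),
#' WOLLF (N=460, DRI at 3m/6m/9m/12m), FASHION (N=348, iHOT-33 at 6m/12m,
#' pilot-then-ramp recruitment), CSAW (N=210, OSS at 6m primary with a
#' late 12m assessment), FIXDT (N=321, DRI at 3m/6m primary with late
#' 12m), and TOPKAT (N=528, OKS at 2m/1y-5y primary, whose five-year
#' primary follow-up exceeds its recruitment span, so its replay window is
#' empty). Correlations and mean trajectories are plausible values of the
#' moderate-to-strong kind seen for such PROMs, not estimates from the
#' trials' data.
#'
#' @param effect treatment benefit added to the test arm at every
#'   occasion, in oriented units (positive = test better); default 0, the
#'   null configuration.
#' @return Named list of [trial_template()] objects.
#' @export
seven_trial_presets <- function(effect = 0) {
  mk_means <- function(control, direction) {
    delta <- if (direction == "lower_better") -effect else effect
    rbind(control = control, test = control + delta)
  }
  tmpl <- function(name, n, labels, offsets, primary, direction, sigma,
                   rho_primary, control_means, start, dur_days,
                   recruitment = NULL, dropout = 0.04, intermittent = 0.03) {
    sched <- outcome_schedule(labels, offsets, primary, direction)
    if (is.null(recruitment))
      recruitment <- data.frame(duration_days = dur_days,
                                rate_per_day = n / dur_days * 1.02)
    L <- length(labels)
    R <- if (L == 1L) matrix(1, 1, 1) else
      .corr_from_primary(rep_len(rho_primary, L - 1L))
    trial_template(
      name, n, sched, recruitment,
      mk_means(control_means, direction),
      covariance_model(stats::setNames(rep(sigma, L), labels), R),
      dropout_hazard = dropout, intermittent_missing_rate = intermittent,
      start_date = as.Date(start))
  }
  list(
    WAT = tmpl("WAT", 126, c("6w", "3m", "6m", "12m"), c(42, 91, 183, 365),
               "12m", "higher_better", 9, c(0.60, 0.72, 0.80),
               c(25, 32, 37, 39), "2007-05-01", 1010),
    DRAFFT = tmpl("DRAFFT", 461, c("3m", "6m", "12m"), c(91, 183, 365),
                  "12m", "lower_better", 20, c(0.62, 0.73),
                  c(40, 25, 15), "2010-07-01", 730),
    WOLLF = tmpl("WOLLF", 460, c("3m", "6m", "9m", "12m"),
                 c(91, 183, 274, 365), "12m", "lower_better", 25,
                 c(0.58, 0.73, 0.80), c(60, 50, 46, 44), "2012-07-01", 1248),
    FASHION = tmpl("FASHION", 348, c("6m", "12m"), c(183, 365), "12m",
                   "higher_better", 20, 0.56, c(45, 50), "2012-07-01", 1460,
                   recruitment = data.frame(
                     duration_days = c(540, 920),
                     rate_per_day = c(348 * 0.15 / 540, 348 * 0.87 / 920))),
    CSAW = tmpl("CSAW", 210, c("6m", "12m"), c(183, 365), "6m",
                "higher_better", 9, 0.75, c(30, 33), "2012-09-01", 1000),
    FIXDT = tmpl("FIXDT", 321, c("3m", "6m", "12m"), c(91, 183, 365), "6m",
                 "lower_better", 20, 0.65, c(45, 32, 25), "2013-04-01", 1095),
    TOPKAT = tmpl("TOPKAT", 528, c("2m", "1y", "2y", "3y", "4y", "5y"),
                  c(61, 365, 730, 1096, 1461, 1826), "5y", "higher_better",
                  9, c(0.55, 0.65, 0.72, 0.78, 0.85),
                  c(28, 35, 36, 37, 37, 37), "2010-01-01", 1340,
                  dropout = 0.03))
}
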