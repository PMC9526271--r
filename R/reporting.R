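# Design configuration, report assembly and operating-characteristics
# simulation: the surface tying the planner, boundary solver, generator and
# replay together (also driven by the thin command-line script shipped in
# inst/cli/gsreplay.R).

#' Group sequential design configuration
#'
#' Everything needed to set up the design before any data exist: the
#' outcome schedule, the expected standard deviations per label (sigma*),
#' a common expected correlation (rho*, default 0.5 reflecting moderate to
#' strong association between occasions), the futility setting and number
#' of interims, the planned accrual per interim, and the monitoring
#' interval.
#'
#' @param schedule an [outcome_schedule()].
#' @param sigma_star named expected SDs per modelled label (a scalar is
#'   applied to all modelled labels).
#' @param rho_star common expected correlation, in (-1, 1); default 0.5.
#' @param setting futility spending setting `"a"`-`"d"`.
#' @param n_interims number of interim analyses (1-3).
#' @param accrual a [planned_accrual()] over the modelled labels.
#' @param monitoring_interval days between monitoring looks (default 14).
#' @return An object of class `design_config`.
#' @export
design_config <- function(schedule, sigma_star, rho_star = 0.5, setting,
                          n_interims, accrual, monitoring_interval = 14L) {
  stopifnot(inherits(schedule, "outcome_schedule"),
            inherits(accrual, "planned_accrual"))
  labels <- modelled_labels(schedule)
  if (length(sigma_star) == 1L && is.null(names(sigma_star)))
    sigma_star <- stats::setNames(rep(sigma_star, length(labels)), labels)
  if (!setequal(names(sigma_star), labels))
    stop("sigma_star must cover exactly the modelled labels")
  if (!is.numeric(rho_star) || abs(rho_star) >= 1)
    stop("rho_star must lie in (-1, 1)")
  if (!setting %in% c("a", "b", "c", "d"))
    stop("setting must be one of 'a', 'b', 'c', 'd'")
  n_interims <- as.integer(n_interims)
  if (n_interims < 1L || n_interims > 3L) stop("n_interims must be 1-3")
  if (!setequal(colnames(accrual), labels))
    stop("accrual labels must match the modelled labels")
  if (nrow(accrual) != n_interims + 1L)
    stop("accrual must have one row per interim plus the final row")
  structure(list(schedule = schedule,
                 sigma_star = sigma_star[labels], rho_star = rho_star,
                 setting = setting, n_interims = n_interims,
                 accrual = accrual,
                 monitoring_interval = as.integer(monitoring_interval)),
            class = "design_config")
}

#' Expected covariance model of a design configuration
#'
#' @param config a [design_config()].
#' @return A [covariance_model()] built from sigma* and the common rho*.
#' @export
expected_cov <- function(config) {
  stopifnot(inherits(config, "design_config"))
  covariance_model(config$sigma_star, config$rho_star)
}

#' Read or write a design configuration as YAML
#'
#' A flat human-editable file that round-trips exactly through
#' [design_config()].
#'
#' @param path file path.
#' @param config a [design_config()] (for writing).
#' @return `read_design_config()` returns a [design_config()];
#'   `write_design_config()` returns `path` invisibly.
#' @export
read_design_config <- function(path) {
  y <- yaml::read_yaml(path)
  sched <- outcome_schedule(y$schedule$labels, y$schedule$offsets_days,
                            y$schedule$primary_label, y$schedule$direction)
  labels <- modelled_labels(sched)
  interims <- y$accrual$interims
  if (!is.list(interims)) interims <- as.list(interims)
  acc_m <- do.call(rbind, lapply(interims, as.numeric))
  design_config(
    schedule = sched,
    sigma_star = stats::setNames(as.numeric(y$sigma_star), labels),
    rho_star = y$rho_star, setting = y$setting, n_interims = y$n_interims,
    accrual = planned_accrual(acc_m, as.numeric(y$accrual$final),
                              labels = labels),
    monitoring_interval = y$monitoring_interval)
}

#' @rdname read_design_config
#' @export
write_design_config <- function(config, path) {
  stopifnot(inherits(config, "design_config"))
  sched <- config$schedule
  K <- config$n_interims
  y <- list(
    schedule = list(labels = sched$labels,
                    offsets_days = as.numeric(sched$offsets_days),
                    primary_label = sched$primary_label,
                    direction = sched$direction),
    sigma_star = as.numeric(config$sigma_star),
    rho_star = config$rho_star,
    setting = config$setting,
    n_interims = K,
    accrual = list(
      interims = lapply(seq_len(K), function(i)
        as.numeric(config$accrual[i, ])),
      final = as.numeric(config$accrual["final", ])),
    monitoring_interval = config$monitoring_interval)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Boundary report for a design configuration
#'
#' Runs the information planner and the boundary solver: expected
#' information per look, information fractions, and the stopping
#' boundaries for the configured spending setting.
#'
#' @param config a [design_config()].
#' @return An object of class `design_report` with `istar`, `fractions`,
#'   `bounds`, `config`.
#' @export
design_report <- function(config) {
  stopifnot(inherits(config, "design_config"))
  istar <- expected_information(config$accrual, expected_cov(config))
  K <- config$n_interims
  fr <- information_fractions(istar[seq_len(K)], istar[K + 1L])
  plan <- make_spending_plan(config$setting, K)
  bounds <- compute_boundaries(plan, as.numeric(istar))
  structure(list(istar = istar, fractions = fr, bounds = bounds,
                 config = config),
            class = "design_report")
}

#' @export
print.design_report <- function(x, digits = 3, ...) {
  cat("Design report (setting ", x$config$setting, ", ",
      x$config$n_interims, " interims)\n", sep = "")
  cat("  expected information I*: ",
      paste(names(x$istar), round(x$istar, digits), sep = "=",
            collapse = ", "), "\n", sep = "")
  print(x$bounds, digits = digits)
  invisible(x)
}

#' Serialize or restore a boundary set as JSON
#'
#' @param bounds a [boundary_set()][compute_boundaries()].
#' @param txt JSON text produced by `boundary_to_json()`.
#' @return `boundary_to_json()` returns a JSON string;
#'   `boundary_from_json()` the restored `boundary_set`.
#' @export
boundary_to_json <- function(bounds) {
  stopifnot(inherits(bounds, "boundary_set"))
  sp <- bounds$spending
  jsonlite::toJSON(list(
    info_levels = bounds$info_levels, lower = bounds$lower,
    upper = bounds$upper, final_crit = bounds$final_crit,
    spending = list(cum_lower = sp$cum_lower, cum_upper = sp$cum_upper,
                    final_lower = sp$final_lower,
                    final_upper = sp$final_upper)),
    digits = NA, auto_unbox = FALSE)
}

#' @rdname boundary_to_json
#' @export
boundary_from_json <- function(txt) {
  j <- jsonlite::fromJSON(txt)
  plan <- spending_plan(j$spending$cum_lower, j$spending$cum_upper,
                        j$spending$final_lower, j$spending$final_upper)
  structure(list(info_levels = as.numeric(j$info_levels),
                 lower = as.numeric(j$lower), upper = as.numeric(j$upper),
                 final_crit = as.numeric(j$final_crit), spending = plan),
            class = "boundary_set")
}

#' JSON report of a replay
#'
#' Machine-readable decision trace: per-interim and final estimates (beta,
#' Z, I and the primary-only beta0, Z0, I0), estimated covariance
#' parameters, counts, months, decisions, and any overrunning estimate.
#'
#' @param res a [replay()] result.
#' @return A JSON string.
#' @export
replay_report_json <- function(res) {
  stopifnot(inherits(res, "gs_replay"))
  est <- function(e) list(beta = e$beta, z = e$z, information = e$information,
                          n_per_label = as.list(e$n_per_label))
  analyses <- lapply(res$interims, function(it) list(
    analysis = paste0("interim_", it$k), date = format(it$date),
    months = it$months, decision = it$decision,
    info_planned = it$info_planned, info_observed = it$info_observed,
    lower = it$lower, upper = it$upper,
    full = est(it$est_full), primary_only = est(it$est_primary),
    sigma_hat = as.list(it$cov$sigmas),
    rho_hat = as.list(as.data.frame(it$cov$correlations))))
  if (!is.null(res$final))
    analyses[[length(analyses) + 1L]] <- list(
      analysis = "final", date = format(res$final$date),
      months = res$final$months,
      decision = if (res$final$reject) "reject" else "accept",
      crit = res$final$crit,
      full = est(res$final$est_full),
      primary_only = est(res$final$est_primary))
  out <- list(
    window = if (res$window$empty) NULL else
      list(start = format(res$window$start), end = format(res$window$end)),
    stopped = res$stopped, stop_reason = res$stop_reason,
    stop_date = if (res$stopped) format(res$stop_date) else NULL,
    analyses = analyses,
    overrun = if (!is.null(res$overrun)) est(res$overrun) else NULL)
  jsonlite::toJSON(out, digits = NA, auto_unbox = TRUE, null = "null")
}

#' Operating characteristics of a design by simulation
#'
#' Repeatedly generates trials from a template and replays them against a
#' boundary set, recording where and why each replication stopped. By
#' default the replay's known-covariance estimator is used with the
#' template's true covariance model, which makes the standardized
#' statistics exactly normal and keeps large runs fast; set
#' `use_template_cov = FALSE` to exercise the maximum-likelihood fit.
#'
#' @param template a [trial_template()].
#' @param bounds a [boundary_set()][compute_boundaries()].
#' @param n_reps number of replications (>= 1).
#' @param seed integer seed; one sub-seed per replication is drawn from it.
#' @param monitoring_interval days between monitoring looks.
#' @param use_template_cov logical, see above.
#' @return An object of class `gs_oc`: `table` (per-look stopping
#'   fractions with binomial SEs), `efficacy_total` (fraction rejecting H0
#'   at any analysis including the final one), `mean_stop_month`,
#'   `mean_stop_n` (over stopped replications), `n_reps`.
#' @export
simulate_oc <- function(template, bounds, n_reps, seed,
                        monitoring_interval = 14L, use_template_cov = TRUE) {
  stopifnot(inherits(template, "trial_template"),
            inherits(bounds, "boundary_set"))
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  set.seed(as.integer(seed))
  seeds <- sample.int(2^31 - 2, n_reps)
  K <- length(bounds$lower)
  look <- integer(n_reps)       # 0 = no stop
  reason <- character(n_reps)
  final_reject <- logical(n_reps)
  stop_month <- stop_n <- rep(NA_real_, n_reps)
  cov <- if (use_template_cov) template$cov else NULL
  for (i in seq_len(n_reps)) {
    d <- generate_trial(template, seeds[i])
    r <- replay(d, bounds, monitoring_interval = monitoring_interval,
                cov = cov, overrun = FALSE, log = FALSE)
    if (r$stopped) {
      it <- r$interims[[length(r$interims)]]
      look[i] <- it$k
      reason[i] <- r$stop_reason
      stop_month[i] <- it$months
      stop_n[i] <- sum(d$participants$randomization_date <= r$stop_date)
    } else {
      reason[i] <- "none"
      final_reject[i] <- isTRUE(r$final$reject)
    }
  }
  tab <- data.frame(
    look = seq_len(K),
    p_futility = vapply(seq_len(K), function(k)
      mean(look == k & reason == "stop_futility"), 0),
    p_efficacy = vapply(seq_len(K), function(k)
      mean(look == k & reason == "stop_efficacy"), 0))
  tab$se_futility <- sqrt(tab$p_futility * (1 - tab$p_futility) / n_reps)
  tab$se_efficacy <- sqrt(tab$p_efficacy * (1 - tab$p_efficacy) / n_reps)
  structure(list(
    table = tab,
    efficacy_total = mean(reason == "stop_efficacy" | final_reject),
    futility_total = mean(reason == "stop_futility"),
    final_reject = mean(final_reject),
    mean_stop_month = mean(stop_month, na.rm = TRUE),
    mean_stop_n = mean(stop_n, na.rm = TRUE),
    n_reps = n_reps, look = look, reason = reason),
    class = "gs_oc")
}

#' @export
print.gs_oc <- function(x, digits = 4, ...) {
  cat("Operating characteristics (", x$n_reps, " replications)\n", sep = "")
  print(round(x$table, digits), row.names = FALSE)
  cat("  total futility stop:", round(x$futility_total, digits),
      "| total efficacy (any analysis):", round(x$efficacy_total, digits),
      "\n")
  if (!is.nan(x$mean_stop_month))
    cat("  mean stopping month:", round(x$mean_stop_month, 1),
        "| mean N at stop:", round(x$mean_stop_n, 1), "\n")
  invisible(x)
}
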