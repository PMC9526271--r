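# Calendar-time replay of a dated trial under a group sequential design:
# biweekly information monitoring inside the window of opportunity,
# interims triggered at pre-set expected information levels, stopping
# decisions against error-spending boundaries, and overrunning analysis of
# the participants recruited before a stop.

#' Window of opportunity for early stopping
#'
#' The window opens at the first date on which a minimum-data rule holds
#' (at least `min_per_arm` participants per arm with an observed primary
#' outcome, and a positive pooled primary-outcome standard deviation) and
#' closes when recruitment completes (the last randomization date). After
#' recruitment ends there is no benefit in stopping, since all recruited
#' participants should complete follow-up. The window can be empty: with
#' long follow-up relative to recruitment, no primary data exist before
#' recruitment ends.
#'
#' @param data a [longitudinal_dataset()].
#' @param min_per_arm minimum per-arm primary-outcome count (default 5).
#' @return A list of class `gs_window` with `start`, `end`, `empty`.
#' @export
window_of_opportunity <- function(data, min_per_arm = 5L) {
  stopifnot(inherits(data, "longitudinal_dataset"))
  end <- max(data$participants$randomization_date)
  prim <- data$records[
    data$records$time_label == data$schedule$primary_label, , drop = FALSE]
  start <- as.Date(NA)
  if (nrow(prim) >= 2L * min_per_arm) {
    d0 <- sort(prim$assessment_date[prim$arm == "control"])
    d1 <- sort(prim$assessment_date[prim$arm == "test"])
    if (length(d0) >= min_per_arm && length(d1) >= min_per_arm) {
      cand <- max(d0[min_per_arm], d1[min_per_arm])
      # advance past dates where the primary outcome has zero variance
      dates <- sort(unique(prim$assessment_date[prim$assessment_date >= cand]))
      for (d in dates) {
        vals <- prim$value[prim$assessment_date <= d]
        arms <- prim$arm[prim$assessment_date <= d]
        centred <- vals - stats::ave(vals, arms)
        if (sum(centred^2) > 0) { start <- as.Date(d, origin = "1970-01-01"); break }
      }
    }
  }
  empty <- is.na(start) || start >= end
  structure(list(start = start, end = end, empty = empty),
            class = "gs_window")
}

#' @export
print.gs_window <- function(x, ...) {
  if (x$empty) cat("Window of opportunity: empty (recruitment ends ",
                   format(x$end), ")\n", sep = "")
  else cat("Window of opportunity: ", format(x$start), " to ",
           format(x$end), "\n", sep = "")
  invisible(x)
}

#' Snapshot of a trial at a calendar date
#'
#' Restricts a dataset to what was known on `date`: participants randomized
#' on or before the date, and assessments dated on or before it.
#'
#' @param data a [longitudinal_dataset()].
#' @param date a `Date` (or coercible).
#' @return A [longitudinal_dataset()] (possibly with zero records).
#' @export
snapshot <- function(data, date) {
  stopifnot(inherits(data, "longitudinal_dataset"))
  date <- as.Date(date)
  part <- data$participants[data$participants$randomization_date <= date, ,
                            drop = FALSE]
  rec <- data$records[data$records$assessment_date <= date &
                        data$records$participant_id %in% part$participant_id, ,
                      drop = FALSE]
  out <- list(records = rec, schedule = data$schedule, participants = part)
  class(out) <- "longitudinal_dataset"
  out
}

# Information path under a fixed covariance model, vectorized over
# monitoring dates: observation-pattern counts per date and arm are built
# by matrix comparisons, and the GLS information of the primary-time
# contrast assembled from per-pattern contribution matrices.
.info_path_fixed <- function(data, cov, dates) {
  sched <- data$schedule
  labels <- modelled_labels(sched)
  L <- length(labels)
  t_idx <- L
  S <- cov_matrix(cov, labels)
  part <- data$participants
  n <- nrow(part)
  rec <- data$records[data$records$time_label %in% labels, , drop = FALSE]
  D <- matrix(NA_real_, n, L)
  D[cbind(match(rec$participant_id, part$participant_id),
          match(rec$time_label, labels))] <- as.numeric(rec$assessment_date)
  arm1 <- part$arm == "test"
  rand <- as.numeric(part$randomization_date)
  nd <- length(dates)
  dn <- as.numeric(dates)
  n_recruited <- findInterval(dn, sort(rand))

  # per-label observation indicator over dates via sorted-date counts
  # (per arm) and, for L > 1, per-pattern-code counts over dates
  counts <- matrix(0L, nd, L, dimnames = list(NULL, labels))
  cnt_arm <- function(x) {  # counts of sorted x at each date
    findInterval(dn, sort(x))
  }
  n0t <- cnt_arm(D[!arm1, t_idx][!is.na(D[!arm1, t_idx])])
  n1t <- cnt_arm(D[arm1, t_idx][!is.na(D[arm1, t_idx])])
  info0 <- ifelse(n0t > 0 & n1t > 0,
                  1 / (S[t_idx, t_idx] * (1 / n0t + 1 / n1t)), NA_real_)

  if (L == 1L) {
    for (j in seq_len(L)) counts[, j] <- n0t + n1t
    info <- ifelse(n0t > 0 & n1t > 0,
                   1 / (S[1, 1] * (1 / n0t + 1 / n1t)), NA_real_)
    return(list(info = info, info0 = info0, counts = counts,
                n_recruited = n_recruited))
  }

  pow <- 2^(seq_len(L) - 1L)
  Dz <- D
  Dz[is.na(Dz)] <- Inf
  # code of each participant at each date: n x nd
  C <- matrix(0L, n, nd)
  for (j in seq_len(L)) {
    C <- C + pow[j] * (outer(Dz[, j], dn, "<="))
    counts[, j] <- colSums(outer(Dz[, j], dn, "<="))
  }
  M_code <- lapply(seq_len(2^L - 1L), function(code) {
    O <- which(bitwAnd(code, pow) > 0L)
    m <- matrix(0, L, L)
    m[O, O] <- solve(S[O, O, drop = FALSE])
    m
  })
  info <- rep(NA_real_, nd)
  cnt <- array(0L, c(2, 2^L - 1L, nd))
  for (code in seq_len(2^L - 1L)) {
    hit <- C == code
    cnt[1, code, ] <- colSums(hit[!arm1, , drop = FALSE])
    cnt[2, code, ] <- colSums(hit[arm1, , drop = FALSE])
  }
  for (i in seq_len(nd)) {
    var_parts <- numeric(2)
    ok <- TRUE
    for (a in 1:2) {
      A <- matrix(0, L, L)
      for (code in seq_len(2^L - 1L)) {
        k <- cnt[a, code, i]
        if (k > 0L) A <- A + k * M_code[[code]]
      }
      if (A[t_idx, t_idx] <= 0) { ok <- FALSE; break }
      est <- which(diag(A) > 0)
      V <- solve(A[est, est, drop = FALSE])
      var_parts[a] <- V[match(t_idx, est), match(t_idx, est)]
    }
    if (ok) info[i] <- 1 / sum(var_parts)
  }
  list(info = info, info0 = info0, counts = counts,
       n_recruited = n_recruited)
}

.fit_at <- function(data, date, cov) {
  snap <- snapshot(data, date)
  if (is.null(cov)) {
    fit <- suppressWarnings(fit_mvn_longitudinal(snap))
    list(full = fit$estimate, primary = suppressWarnings(fit_primary_only(snap)),
         cov = fit$cov)
  } else {
    list(full = estimate_with_fixed_cov(snap, cov),
         primary = suppressWarnings(fit_primary_only(snap)),
         cov = cov)
  }
}

#' Replay a dated trial against group sequential boundaries
#'
#' Walks a biweekly monitoring grid through the window of opportunity. At
#' each monitoring date the longitudinal model is fitted to the snapshot of
#' data available on that date and the observed information `I` recorded;
#' when `I` reaches the next planned information level the interim analysis
#' is conducted: the standardized statistic is compared with that look's
#' boundaries (`Z <= l_k` stops for futility, `Z >= u_k` for efficacy).
#' Boundaries are *not* re-solved at the observed information; the design
#' levels are used as planned. If the window closes without a stop, the
#' final analysis is performed on the complete data against the final
#' critical value. If the trial stops, an overrunning analysis re-estimates
#' the effect from the complete eventual follow-up of all participants
#' recruited by the stop date. Interim triggering always uses the
#' full-model information `I`; the primary-only `I0` is logged alongside
#' for comparison.
#'
#' @param data a [longitudinal_dataset()].
#' @param bounds a [boundary_set()][compute_boundaries()]; its
#'   `info_levels` are the trigger levels (interims then final).
#' @param monitoring_interval days between monitoring looks (default 14).
#' @param cov optional [covariance_model()]: when supplied the model is
#'   estimated by generalized least squares with this covariance treated as
#'   known (fast, exact-normal statistics, used for operating
#'   characteristics); when `NULL` (default) the maximum-likelihood
#'   longitudinal fit is used at every monitoring date.
#' @param min_per_arm minimum-data rule passed to
#'   [window_of_opportunity()].
#' @param overrun run the overrunning analysis after a stop (default TRUE).
#' @param log keep the full monitoring log (default TRUE; turn off in large
#'   simulations).
#' @return An object of class `gs_replay`: list with `window`, `log`
#'   (monitoring data frame), `interims` (list of per-interim records with
#'   estimates, boundaries and decision), `stopped`, `stop_reason`,
#'   `stop_date`, `final` (final-analysis record or NULL), `overrun`
#'   (overrunning [effect_estimate()] or NULL), `months_at_end`.
#' @export
replay <- function(data, bounds, monitoring_interval = 14L, cov = NULL,
                   min_per_arm = 5L, overrun = TRUE, log = TRUE) {
  stopifnot(inherits(data, "longitudinal_dataset"),
            inherits(bounds, "boundary_set"))
  K <- length(bounds$lower)
  istar <- bounds$info_levels
  origin <- min(data$participants$randomization_date)
  window <- window_of_opportunity(data, min_per_arm = min_per_arm)
  interims <- list()
  stopped <- FALSE
  stop_reason <- NA_character_
  stop_date <- as.Date(NA)
  logdf <- NULL

  if (!window$empty && K > 0L) {
    grid <- seq(window$start, window$end, by = monitoring_interval)
    if (!is.null(cov)) {
      path <- .info_path_fixed(data, cov, grid)
      info_seq <- path$info
      if (log)
        logdf <- data.frame(date = grid, n_recruited = path$n_recruited,
                            path$counts, info = path$info,
                            info0 = path$info0, check.names = FALSE)
    } else {
      info_seq <- rep(NA_real_, length(grid))
      if (log) {
        labels <- modelled_labels(data$schedule)
        cmat <- matrix(NA_integer_, length(grid), length(labels),
                       dimnames = list(NULL, labels))
        nrec <- integer(length(grid))
        i0 <- rep(NA_real_, length(grid))
      }
      fits <- vector("list", length(grid))
      for (i in seq_along(grid)) {
        f <- tryCatch(.fit_at(data, grid[i], NULL), error = function(e) NULL)
        if (is.null(f)) {
          warning("model fit failed at ", format(grid[i]), "; date skipped")
        } else {
          fits[[i]] <- f
          info_seq[i] <- f$full$information
        }
        if (log) {
          snap <- snapshot(data, grid[i])
          nrec[i] <- nrow(snap$participants)
          cmat[i, ] <- n_per_label(snap)[colnames(cmat)]
          if (!is.null(f)) i0[i] <- f$primary$information
        }
      }
      if (log)
        logdf <- data.frame(date = grid, n_recruited = nrec, cmat,
                            info = info_seq, info0 = i0, check.names = FALSE)
    }

    k <- 1L
    for (i in seq_along(grid)) {
      if (is.na(info_seq[i])) next
      while (k <= K && info_seq[i] >= istar[k]) {
        f <- .fit_at(data, grid[i], cov)
        z <- f$full$z
        decision <- if (z <= bounds$lower[k]) "stop_futility"
          else if (z >= bounds$upper[k]) "stop_efficacy" else "continue"
        interims[[k]] <- list(
          k = k, date = grid[i],
          months = .months_since(grid[i], origin),
          info_observed = info_seq[i], info_planned = istar[k],
          est_full = f$full, est_primary = f$primary, cov = f$cov,
          lower = bounds$lower[k], upper = bounds$upper[k],
          decision = decision)
        if (decision != "continue") {
          stopped <- TRUE
          stop_reason <- decision
          stop_date <- grid[i]
        }
        k <- k + 1L
        if (stopped) break
      }
      if (stopped || k > K) break
    }
  }

  final <- NULL
  if (!stopped) {
    end_date <- max(data$records$assessment_date)
    f <- .fit_at(data, end_date, cov)
    final <- list(date = end_date,
                  months = .months_since(end_date, origin),
                  est_full = f$full, est_primary = f$primary, cov = f$cov,
                  crit = bounds$final_crit,
                  reject = f$full$z >= bounds$final_crit)
  }

  res <- structure(
    list(window = window, log = logdf, interims = interims,
         stopped = stopped, stop_reason = stop_reason, stop_date = stop_date,
         final = final, overrun = NULL, bounds = bounds, cov_mode = cov,
         origin = origin),
    class = "gs_replay")
  if (stopped && overrun) res$overrun <- overrun_analysis(data, res)
  res
}

#' Overrunning analysis after an early stop
#'
#' Re-estimates the treatment effect from the complete eventual follow-up
#' (all assessments, whenever dated) of the participants recruited on or
#' before the stop date. Quantifies what the trial would eventually have
#' concluded about those already randomized when it stopped.
#'
#' @param data the full [longitudinal_dataset()] the replay was run on.
#' @param replay_result a stopped [replay()] result.
#' @return An [effect_estimate()].
#' @export
overrun_analysis <- function(data, replay_result) {
  stopifnot(inherits(replay_result, "gs_replay"))
  if (!replay_result$stopped)
    stop("overrunning analysis requires a replay that stopped at an interim")
  keep <- data$participants$randomization_date <= replay_result$stop_date
  part <- data$participants[keep, , drop = FALSE]
  rec <- data$records[data$records$participant_id %in% part$participant_id, ,
                      drop = FALSE]
  sub <- list(records = rec, schedule = data$schedule, participants = part)
  class(sub) <- "longitudinal_dataset"
  if (is.null(replay_result$cov_mode)) {
    suppressWarnings(fit_mvn_longitudinal(sub))$estimate
  } else {
    estimate_with_fixed_cov(sub, replay_result$cov_mode)
  }
}

.months_since <- function(date, origin) {
  as.integer(round(as.numeric(as.Date(date) - as.Date(origin)) / 30.44))
}

#' @export
print.gs_replay <- function(x, digits = 2, ...) {
  cat("Group sequential replay\n")
  print(x$window)
  for (it in x$interims) {
    cat(sprintf(
      "  interim %d (%s, month %d): beta = %.*f, Z = %.*f, I = %.3f (planned %.3f), [%.*f, %.*f] -> %s\n",
      it$k, format(it$date), it$months, digits, it$est_full$beta, digits,
      it$est_full$z, it$info_observed, it$info_planned, digits, it$lower,
      digits, it$upper, it$decision))
  }
  if (!is.null(x$final)) {
    cat(sprintf("  final (%s, month %d): beta = %.*f, Z = %.*f, crit = %.*f -> %s\n",
                format(x$final$date), x$final$months, digits,
                x$final$est_full$beta, digits, x$final$est_full$z, digits,
                x$final$crit,
                if (x$final$reject) "reject H0" else "do not reject H0"))
  }
  if (!is.null(x$overrun))
    cat(sprintf("  overrunning: beta = %.*f, Z = %.*f, I = %.3f\n", digits,
                x$overrun$beta, digits, x$overrun$z, x$overrun$information))
  invisible(x)
}

#' Tabular summary of a replay
#'
#' One row per conducted analysis with the fields reported for the
#' simulated designs: effect estimates and test statistics with and
#' without borrowing from early outcomes, information, per-label counts,
#' recruitment and months elapsed.
#'
#' @param object a [replay()] result.
#' @param ... unused.
#' @return A data frame.
#' @export
summary.gs_replay <- function(object, ...) {
  rows <- list()
  fmt <- function(tag, date, months, full, prim, decision) {
    npl <- full$n_per_label
    data.frame(analysis = tag, date = as.Date(date), months = months,
               beta = full$beta, z = full$z, info = full$information,
               beta0 = prim$beta, z0 = prim$z, info0 = prim$information,
               n_primary = unname(prim$n_per_label[1]),
               n_total_obs = sum(npl), decision = decision)
  }
  for (it in object$interims)
    rows[[length(rows) + 1L]] <- fmt(paste0("interim_", it$k), it$date,
                                     it$months, it$est_full, it$est_primary,
                                     it$decision)
  if (!is.null(object$final))
    rows[[length(rows) + 1L]] <- fmt("final", object$final$date,
                                     object$final$months,
                                     object$final$est_full,
                                     object$final$est_primary,
                                     if (object$final$reject) "reject"
                                     else "accept")
  do.call(rbind, rows)
}
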