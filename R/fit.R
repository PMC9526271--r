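# Longitudinal multivariate-normal model for two-arm trials with
# incomplete follow-up. The model is Y_i ~ MVN(mu_{arm(i)}, Sigma) over the
# modelled occasions, with saturated per-arm per-occasion means and a single
# unstructured Sigma shared by the arms; the likelihood is formed per
# observed-missingness pattern (missing at random).

# Wide-format view over the modelled labels: participants with at least one
# modelled observation, their arm, and an n-by-L value matrix with NAs.
.wide_data <- function(data, labels = modelled_labels(data$schedule)) {
  part <- data$participants
  rec <- data$records[data$records$time_label %in% labels, , drop = FALSE]
  Y <- matrix(NA_real_, nrow = nrow(part), ncol = length(labels),
              dimnames = list(part$participant_id, labels))
  if (nrow(rec)) {
    Y[cbind(match(rec$participant_id, part$participant_id),
            match(rec$time_label, labels))] <- rec$value
  }
  keep <- rowSums(!is.na(Y)) > 0
  list(Y = Y[keep, , drop = FALSE], arm = part$arm[keep], labels = labels)
}

.orient <- function(beta_raw, direction) {
  if (direction == "lower_better") -beta_raw else beta_raw
}

.check_primary_counts <- function(y, arm, min_n = 2L) {
  obs <- !is.na(y)
  n1 <- sum(obs & arm == "test")
  n0 <- sum(obs & arm == "control")
  if (n1 < min_n || n0 < min_n)
    stop("information undefined: fewer than ", min_n,
         " primary-outcome values in an arm (control = ", n0,
         ", test = ", n1, ")")
  c(control = n0, test = n1)
}

# Integer code of an observation pattern (bitmask over labels).
.pattern_codes <- function(obs) {
  as.integer(obs %*% 2^(seq_len(ncol(obs)) - 1L))
}

# Per-arm GLS information matrices A_a = sum_i E_i' Sigma_{O_iO_i}^{-1} E_i
# and score vectors b_a = sum_i E_i' Sigma_{O_iO_i}^{-1} y_{O_i}.
.gls_accumulate <- function(Y, arm, S) {
  L <- ncol(Y)
  obs <- !is.na(Y)
  codes <- .pattern_codes(obs)
  out <- list(control = list(A = matrix(0, L, L), b = numeric(L)),
              test = list(A = matrix(0, L, L), b = numeric(L)))
  for (code in unique(codes)) {
    idx <- which(codes == code)
    O <- which(bitwAnd(code, 2^(seq_len(L) - 1L)) > 0L)
    W <- solve(S[O, O, drop = FALSE])
    for (a in c("control", "test")) {
      rows <- idx[arm[idx] == a]
      if (!length(rows)) next
      out[[a]]$A[O, O] <- out[[a]]$A[O, O] + length(rows) * W
      ysum <- colSums(Y[rows, O, drop = FALSE])
      out[[a]]$b[O] <- out[[a]]$b[O] + as.numeric(W %*% ysum)
    }
  }
  out
}

# Variance of the primary-time arm contrast given Sigma and the observed
# missingness patterns (plug-in GLS variance); also the per-arm GLS means.
.gls_solve <- function(acc, labels, primary) {
  t_idx <- match(primary, labels)
  mu <- matrix(NA_real_, 2, length(labels),
               dimnames = list(c("control", "test"), labels))
  var_parts <- numeric(2)
  for (j in c(1, 2)) {
    a <- c("control", "test")[j]
    A <- acc[[a]]$A
    est <- which(diag(A) > 0)
    if (!(t_idx %in% est))
      stop("information undefined: no primary-outcome data in the ", a, " arm")
    V <- solve(A[est, est, drop = FALSE])
    mu[a, est] <- as.numeric(V %*% acc[[a]]$b[est])
    var_parts[j] <- V[match(t_idx, est), match(t_idx, est)]
  }
  list(mu = mu, variance = sum(var_parts))
}

#' Primary-outcome-only treatment effect (correlations forced to zero)
#'
#' The comparison analysis that uses final-outcome data only: the
#' difference in arm means of the primary outcome, with variance
#' `sigma_t^2 (1/n1 + 1/n0)` where `sigma_t` is the pooled maximum-
#' likelihood (1/n divisor) standard deviation. Its information is the `I0`
#' accompanying the full-model `I`.
#'
#' @param data a [longitudinal_dataset()].
#' @return An [effect_estimate()] with `mode = "primary_only"`.
#' @export
fit_primary_only <- function(data) {
  stopifnot(inherits(data, "longitudinal_dataset"))
  sched <- data$schedule
  w <- .wide_data(data, labels = sched$primary_label)
  y <- w$Y[, 1]
  n <- .check_primary_counts(y, w$arm)
  m0 <- mean(y[w$arm == "control"], na.rm = TRUE)
  m1 <- mean(y[w$arm == "test"], na.rm = TRUE)
  yv <- y[!is.na(y)]
  av <- w$arm[!is.na(y)]
  sig2 <- sum((yv - ifelse(av == "test", m1, m0))^2) / length(yv)
  if (sig2 <= 0) stop("information undefined: primary outcome has zero variance")
  variance <- sig2 * (1 / n["test"] + 1 / n["control"])
  gm <- matrix(c(m0, m1), 2, 1,
               dimnames = list(c("control", "test"), sched$primary_label))
  effect_estimate(.orient(m1 - m0, sched$direction), variance,
                  mode = "primary_only", group_means = gm,
                  n_per_label = stats::setNames(sum(n), sched$primary_label),
                  method = "pooled_ml")
}

#' Treatment effect by generalized least squares with known covariance
#'
#' Estimates the per-arm occasion means and the primary-time treatment
#' effect treating the covariance model as known, weighting each
#' participant's observed sub-vector by the inverse of the corresponding
#' block of Sigma. The variance is exact given Sigma and the observed
#' missingness patterns. This is the inner step shared by the information
#' planner and by the replay's known-covariance mode.
#'
#' @param data a [longitudinal_dataset()].
#' @param cov a [covariance_model()] covering every modelled label.
#' @return An [effect_estimate()] with `mode = "full"` (or
#'   `"primary_only"` when a single occasion is modelled).
#' @export
estimate_with_fixed_cov <- function(data, cov) {
  stopifnot(inherits(data, "longitudinal_dataset"),
            inherits(cov, "covariance_model"))
  sched <- data$schedule
  labels <- modelled_labels(sched)
  if (!all(labels %in% names(cov$sigmas)))
    stop("covariance model does not cover modelled labels: ",
         paste(setdiff(labels, names(cov$sigmas)), collapse = ", "))
  S <- cov_matrix(cov, labels)
  w <- .wide_data(data, labels)
  .check_primary_counts(w$Y[, match(sched$primary_label, labels)], w$arm)
  acc <- .gls_accumulate(w$Y, w$arm, S)
  sol <- .gls_solve(acc, labels, sched$primary_label)
  beta_raw <- sol$mu["test", sched$primary_label] -
    sol$mu["control", sched$primary_label]
  effect_estimate(.orient(beta_raw, sched$direction), sol$variance,
                  mode = if (length(labels) > 1L) "full" else "primary_only",
                  group_means = sol$mu,
                  n_per_label = colSums(!is.na(w$Y)),
                  method = "gls_fixed_cov")
}

# Available-case starting values: per-arm per-label means, pooled
# within-arm variances, pairwise within-arm correlations (0, with a
# warning, for label pairs never jointly observed).
.em_init <- function(Y, arm, labels) {
  L <- ncol(Y)
  mu <- matrix(0, 2, L, dimnames = list(c("control", "test"), labels))
  for (a in c("control", "test")) {
    m <- colMeans(Y[arm == a, , drop = FALSE], na.rm = TRUE)
    overall <- colMeans(Y, na.rm = TRUE)
    m[is.nan(m)] <- overall[is.nan(m)]
    m[is.nan(m)] <- 0
    mu[a, ] <- m
  }
  Yc <- Y - mu[match(arm, c("control", "test")), , drop = FALSE]
  sig2 <- apply(Yc, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(1)
    max(sum(x^2) / length(x), 1e-8)
  })
  R <- diag(1, L)
  inestimable <- FALSE
  if (L > 1L) {
    for (j in 1:(L - 1)) for (k in (j + 1):L) {
      both <- !is.na(Yc[, j]) & !is.na(Yc[, k])
      if (sum(both) >= 2L) {
        num <- sum(Yc[both, j] * Yc[both, k])
        den <- sqrt(sum(Yc[both, j]^2) * sum(Yc[both, k]^2))
        r <- if (den > 0) num / den else 0
        R[j, k] <- R[k, j] <- max(min(r, 0.99), -0.99)
      } else {
        inestimable <- TRUE
      }
    }
  }
  if (inestimable)
    warning("some label pairs have no jointly observed participants; ",
            "their starting correlations are set to 0")
  R <- repair_correlation(R)
  list(mu = mu, Sigma = R * tcrossprod(sqrt(sig2)))
}

#' Maximum-likelihood longitudinal model fit
#'
#' Fits the two-arm multivariate-normal model with saturated per-arm means
#' and one unstructured covariance matrix to possibly incomplete outcome
#' data, by an EM algorithm over the observed-missingness patterns
#' (missing-at-random likelihood). The treatment effect is the primary-time
#' arm contrast; its variance is the plug-in generalized-least-squares
#' variance at the estimated Sigma given the observed patterns, so that the
#' reported information matches the known-covariance planning formulas.
#'
#' Labels with fewer than two observed values are dropped from the model
#' with a warning. Estimated correlation matrices that are not positive
#' definite are repaired by eigenvalue clipping.
#'
#' @param data a [longitudinal_dataset()].
#' @param tol relative convergence tolerance on the observed-data
#'   log-likelihood (default `1e-8`).
#' @param max_iter maximum EM iterations.
#' @param start optional `covariance_model` used as the starting Sigma.
#' @return A list of class `gs_fit` with elements `estimate` (an
#'   [effect_estimate()], `mode = "full"`), `cov` (a [covariance_model()]
#'   holding the ML sigma-hats and rho-hats), `mu` (arm-by-label means),
#'   `loglik`, `iterations`, `labels`.
#' @export
fit_mvn_longitudinal <- function(data, tol = 1e-8, max_iter = 1000L,
                                 start = NULL) {
  stopifnot(inherits(data, "longitudinal_dataset"))
  sched <- data$schedule
  labels <- modelled_labels(sched)
  w <- .wide_data(data, labels)
  n_obs <- colSums(!is.na(w$Y))
  thin <- labels[n_obs < 2L & labels != sched$primary_label]
  if (length(thin)) {
    warning("dropping labels with fewer than 2 observations: ",
            paste(thin, collapse = ", "))
    labels <- setdiff(labels, thin)
    w <- .wide_data(data, labels)
  }
  Y <- w$Y
  arm <- w$arm
  L <- ncol(Y)
  n <- nrow(Y)
  t_idx <- match(sched$primary_label, labels)
  .check_primary_counts(Y[, t_idx], arm)

  init <- .em_init(Y, arm, labels)
  mu <- init$mu
  Sigma <- init$Sigma
  if (!is.null(start)) Sigma <- cov_matrix(start, labels)

  obs <- !is.na(Y)
  codes <- .pattern_codes(obs)
  groups <- split(seq_len(n), codes)
  arm_idx <- match(arm, c("control", "test"))
  ll_old <- -Inf
  iter <- 0L
  repaired <- FALSE
  repeat {
    iter <- iter + 1L
    Yhat <- Y
    Csum <- matrix(0, L, L)
    ll <- 0
    for (g in groups) {
      O <- which(obs[g[1], ])
      M <- setdiff(seq_len(L), O)
      SOO <- Sigma[O, O, drop = FALSE]
      ch <- chol(SOO)
      W <- chol2inv(ch)
      resid <- Y[g, O, drop = FALSE] - mu[arm_idx[g], O, drop = FALSE]
      ll <- ll - 0.5 * length(g) * (2 * sum(log(diag(ch))) +
                                      length(O) * log(2 * pi)) -
        0.5 * sum((resid %*% W) * resid)
      if (length(M)) {
        B <- Sigma[M, O, drop = FALSE] %*% W
        Yhat[g, M] <- mu[arm_idx[g], M, drop = FALSE] +
          resid %*% t(B)
        Cp <- Sigma[M, M, drop = FALSE] - B %*% Sigma[O, M, drop = FALSE]
        Csum[M, M] <- Csum[M, M] + length(g) * Cp
      }
    }
    # M-step
    for (a in 1:2) mu[a, ] <- colMeans(Yhat[arm_idx == a, , drop = FALSE])
    Xc <- Yhat - mu[arm_idx, , drop = FALSE]
    Sigma_new <- (crossprod(Xc) + Csum) / n
    ev <- eigen(Sigma_new, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev)) {
      repaired <- TRUE
      s <- sqrt(pmax(diag(Sigma_new), 1e-8))
      R <- repair_correlation(Sigma_new / tcrossprod(s))
      Sigma_new <- R * tcrossprod(s)
    }
    Sigma <- Sigma_new
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    if (iter >= max_iter) {
      warning("EM did not converge in ", max_iter, " iterations")
      break
    }
    ll_old <- ll
  }
  if (repaired)
    warning("estimated covariance repaired to positive definiteness")

  dimnames(Sigma) <- list(labels, labels)
  acc <- .gls_accumulate(Y, arm, Sigma)
  sol <- .gls_solve(acc, labels, sched$primary_label)
  beta_raw <- mu["test", t_idx] - mu["control", t_idx]
  est <- effect_estimate(.orient(beta_raw, sched$direction), sol$variance,
                         mode = "full", group_means = mu,
                         n_per_label = colSums(!is.na(Y)),
                         method = "ml_em")
  sig <- sqrt(diag(Sigma))
  covm <- covariance_model(stats::setNames(sig, labels),
                           Sigma / tcrossprod(sig))
  structure(list(estimate = est, cov = covm, mu = mu, loglik = ll,
                 iterations = iter, labels = labels),
            class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat("Longitudinal MVN fit (", x$iterations, " EM iterations, loglik ",
      format(x$loglik), ")\n", sep = "")
  print(x$estimate)
  print(x$cov)
  invisible(x)
}
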