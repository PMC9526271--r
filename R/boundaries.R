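# Error-spending stopping boundaries for sequential standardized test
# statistics. Under the canonical joint law, (Z_1, ..., Z_K) is
# multivariate normal with cov(Z_j, Z_k) = sqrt(I_j / I_k) for j <= k and
# mean E[Z_k] = drift * sqrt(I_k); boundaries are solved look by look so
# that the exit probabilities under the null match the cumulative spending
# plan, propagating the subdensity of continuing paths on a Gauss-Legendre
# grid. Futility boundaries are treated as binding.

#' Cumulative error-spending plan
#'
#' The cumulative probabilities, under the null hypothesis, of having
#' stopped for futility (`cum_lower`) and of having stopped and rejected
#' the null for efficacy (`cum_upper`) by each interim analysis. At the end
#' of the trial the cumulative probabilities are 0.975 and 0.025, so the
#' overall two-sided-equivalent one-sided type-I error is 2.5%.
#'
#' @param cum_lower strictly increasing cumulative futility probabilities,
#'   one per interim (may be length 0 for a design with no interims).
#' @param cum_upper strictly increasing cumulative efficacy probabilities,
#'   one per interim.
#' @param final_lower,final_upper cumulative probabilities at the final
#'   analysis (defaults 0.975 and 0.025).
#' @return An object of class `spending_plan`.
#' @seealso [make_spending_plan()] for the preset futility settings a-d.
#' @export
spending_plan <- function(cum_lower, cum_upper,
                          final_lower = 0.975, final_upper = 0.025) {
  cum_lower <- as.numeric(cum_lower)
  cum_upper <- as.numeric(cum_upper)
  if (length(cum_lower) != length(cum_upper))
    stop("cum_lower and cum_upper must have the same length")
  K <- length(cum_lower)
  if (K > 0L) {
    if (any(diff(cum_lower) <= 0) || any(diff(cum_upper) <= 0))
      stop("cumulative spending must be strictly increasing across looks")
    if (any(cum_lower <= 0) || any(cum_upper <= 0))
      stop("cumulative spending must be positive")
    if (any(cum_lower + cum_upper >= 1))
      stop("cum_lower + cum_upper must be below 1 at every look")
    if (cum_lower[K] >= final_lower || cum_upper[K] >= final_upper)
      stop("interim spending must stay below the final values")
  }
  if (abs(final_lower + final_upper - 1) > 1e-12)
    stop("final_lower + final_upper must equal 1")
  structure(list(n_interims = K, cum_lower = cum_lower,
                 cum_upper = cum_upper, final_lower = final_lower,
                 final_upper = final_upper),
            class = "spending_plan")
}

# Preset cumulative futility probabilities by number of interims; the
# efficacy spends are shared across the four settings.
.spend_presets <- list(
  `1` = list(lower = matrix(c(0.160, 0.320, 0.480, 0.640), 1, 4,
                            dimnames = list(NULL, c("a", "b", "c", "d"))),
             upper = 0.005),
  `2` = list(lower = matrix(c(0.080, 0.160, 0.240, 0.320,
                              0.160, 0.320, 0.480, 0.640), 2, 4,
                            byrow = TRUE,
                            dimnames = list(NULL, c("a", "b", "c", "d"))),
             upper = c(0.001, 0.010)),
  `3` = list(lower = matrix(c(0.080, 0.160, 0.240, 0.320,
                              0.160, 0.320, 0.480, 0.640,
                              0.240, 0.480, 0.720, 0.960), 3, 4,
                            byrow = TRUE,
                            dimnames = list(NULL, c("a", "b", "c", "d"))),
             upper = c(0.001, 0.005, 0.010)))

#' Preset futility/efficacy spending settings (a-d)
#'
#' Four increasingly aggressive futility-stopping settings for one, two or
#' three interim analyses. Setting (a) spends futility probability slowly
#' (e.g. 0.160 by a single interim); setting (d) aggressively (0.960
#' cumulative by the third of three interims). The efficacy spends are
#' deliberately small at interims (at most 0.010 cumulative), reflecting a
#' design that stops early mainly for futility, and always total 0.025.
#'
#' @param setting one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param n_interims number of interim analyses, 1 to 3.
#' @return A [spending_plan()].
#' @examples
#' make_spending_plan("a", 1)  # cum_lower 0.160, cum_upper 0.005
#' make_spending_plan("d", 3)  # cum_lower 0.320, 0.640, 0.960
#' @export
make_spending_plan <- function(setting = c("a", "b", "c", "d"), n_interims) {
  setting <- match.arg(setting)
  n_interims <- as.integer(n_interims)
  if (is.na(n_interims) || n_interims < 1L || n_interims > 3L)
    stop("n_interims must be 1, 2 or 3")
  p <- .spend_presets[[as.character(n_interims)]]
  spending_plan(p$lower[, setting], p$upper)
}

#' @export
print.spending_plan <- function(x, ...) {
  cat("Spending plan:", x$n_interims, "interim analyses\n")
  if (x$n_interims > 0L)
    print(data.frame(look = seq_len(x$n_interims),
                     cum_lower = x$cum_lower, cum_upper = x$cum_upper))
  cat("  final:", x$final_lower, "/", x$final_upper, "\n")
  invisible(x)
}

# Transition Z_k | Z_{k-1} = x is normal with mean x * sqrt(I_{k-1}/I_k) +
# drift * (I_k - I_{k-1}) / sqrt(I_k) and variance 1 - I_{k-1}/I_k.
.transition <- function(info_prev, info_next, drift) {
  r <- sqrt(info_prev / info_next)
  list(r = r, shift = drift * (info_next - info_prev) / sqrt(info_next),
       sd = sqrt(1 - r^2))
}

#' Compute stopping boundaries from a spending plan
#'
#' Solves, look by look, for the lower (futility) and upper (efficacy)
#' critical values of the standardized test statistics such that the exit
#' probabilities under the null hypothesis equal the increments of the
#' cumulative spending plan, with futility boundaries binding. The final
#' critical value is set so the cumulative efficacy spend is exactly
#' `final_upper`. The subdensity of continuing sample paths is propagated
#' on a Gauss-Legendre grid over each continuation interval; boundary
#' values are found by root finding on the exit probability.
#'
#' @param plan a [spending_plan()].
#' @param info_levels planned information levels, strictly increasing, of
#'   length `n_interims + 1` (interims then final).
#' @param nodes number of Gauss-Legendre nodes per look (default 256).
#' @param interval search interval for critical values on the Z scale.
#' @return An object of class `boundary_set` with elements `info_levels`,
#'   `lower`, `upper` (length `n_interims`), `final_crit`, `spending`.
#' @examples
#' b <- compute_boundaries(make_spending_plan("a", 1), c(0.5, 1))
#' b$lower  # qnorm(0.160)
#' b$upper  # qnorm(0.995)
#' @export
compute_boundaries <- function(plan, info_levels, nodes = 256L,
                               interval = c(-15, 15)) {
  stopifnot(inherits(plan, "spending_plan"))
  info_levels <- as.numeric(info_levels)
  K <- plan$n_interims
  if (length(info_levels) != K + 1L)
    stop("info_levels must have length n_interims + 1 (interims then final)")
  if (any(info_levels <= 0) || any(diff(info_levels) <= 0))
    stop("info_levels must be positive and strictly increasing")

  lower <- upper <- numeric(K)
  grid <- NULL  # list(x, w, psi) over the current continuation region
  inc_upper <- diff(c(0, plan$cum_upper, plan$final_upper))
  inc_lower <- diff(c(0, plan$cum_lower))

  upper_exit <- function(u, grid, tr) {
    sum(grid$w * grid$psi * stats::pnorm((grid$x * tr$r + tr$shift - u) / tr$sd))
  }
  lower_exit <- function(l, grid, tr) {
    sum(grid$w * grid$psi * stats::pnorm((l - grid$x * tr$r - tr$shift) / tr$sd))
  }
  solve_crit <- function(f, target, look) {
    if (target <= 0)
      stop("incremental spend must be positive (look ", look, ")")
    g <- function(z) f(z) - target
    if (g(interval[1]) * g(interval[2]) > 0)
      stop("spending exceeds the probability of reaching look ", look,
           "; boundaries overlap")
    stats::uniroot(g, interval, tol = 1e-12)$root
  }

  for (k in seq_len(K)) {
    if (k == 1L) {
      # first-look exits are marginal normal probabilities
      upper[1] <- stats::qnorm(1 - inc_upper[1])
      lower[1] <- stats::qnorm(inc_lower[1])
      if (inc_upper[1] <= 0 || inc_lower[1] <= 0)
        stop("incremental spend must be positive (look 1)")
    } else {
      tr <- .transition(info_levels[k - 1], info_levels[k], 0)
      upper[k] <- solve_crit(function(u) upper_exit(u, grid, tr),
                             inc_upper[k], k)
      lower[k] <- solve_crit(function(l) lower_exit(l, grid, tr),
                             inc_lower[k], k)
    }
    if (lower[k] >= upper[k])
      stop("lower boundary meets upper boundary at look ", k,
           "; spending is too aggressive at this information level")
    grid <- .propagate(grid, lower[k], upper[k], nodes,
                       if (k == 1L) NULL else
                         .transition(info_levels[k - 1], info_levels[k], 0),
                       drift = 0, info_first = info_levels[1])
  }

  if (K == 0L) {
    final_crit <- stats::qnorm(1 - plan$final_upper)
  } else {
    tr <- .transition(info_levels[K], info_levels[K + 1], 0)
    final_crit <- solve_crit(function(u) upper_exit(u, grid, tr),
                             inc_upper[K + 1], K + 1)
  }
  structure(list(info_levels = info_levels, lower = lower, upper = upper,
                 final_crit = final_crit, spending = plan),
            class = "boundary_set")
}

# Gauss-Legendre subdensity over [l, u]: at the first look the subdensity
# is the N(drift * sqrt(I_1), 1) density; afterwards it is propagated
# through the transition kernel from the previous grid.
.propagate <- function(grid, l, u, nodes, tr, drift, info_first) {
  gl <- pracma::gaussLegendre(nodes, l, u)
  psi <- if (is.null(grid)) {
    stats::dnorm(gl$x - drift * sqrt(info_first))
  } else {
    m <- outer(gl$x, grid$x * tr$r + tr$shift, "-") / tr$sd
    as.numeric((stats::dnorm(m) / tr$sd) %*% (grid$w * grid$psi))
  }
  list(x = gl$x, w = gl$w, psi = psi)
}

#' Exit probabilities of a boundary set
#'
#' Computes, by the same grid recursion used to construct the boundaries,
#' the probability of exiting below (futility) and above (efficacy) at each
#' look and at the final analysis, under a drift `theta` defined as the
#' effect per unit square-root information, so `E[Z_k] = theta * sqrt(I_k)`.
#' With `drift = 0` the spending plan is reproduced up to solver tolerance.
#'
#' @param bounds a [boundary_set()][compute_boundaries()].
#' @param drift canonical drift parameter (default 0, the null).
#' @param nodes Gauss-Legendre nodes per look.
#' @return A data frame with one row per look plus the final analysis:
#'   `look`, `info`, `lower`, `upper`, `p_lower`, `p_upper`, and attributes
#'   `total_lower`, `total_upper` (the totals sum to 1).
#' @export
exit_probabilities <- function(bounds, drift = 0, nodes = 256L) {
  stopifnot(inherits(bounds, "boundary_set"))
  K <- length(bounds$lower)
  info <- bounds$info_levels
  p_lower <- p_upper <- numeric(K + 1)
  grid <- NULL
  for (k in seq_len(K)) {
    if (k == 1L) {
      mu1 <- drift * sqrt(info[1])
      p_upper[1] <- stats::pnorm(mu1 - bounds$upper[1])
      p_lower[1] <- stats::pnorm(bounds$lower[1] - mu1)
      tr <- NULL
    } else {
      tr <- .transition(info[k - 1], info[k], drift)
      p_upper[k] <- sum(grid$w * grid$psi *
                          stats::pnorm((grid$x * tr$r + tr$shift - bounds$upper[k]) / tr$sd))
      p_lower[k] <- sum(grid$w * grid$psi *
                          stats::pnorm((bounds$lower[k] - grid$x * tr$r - tr$shift) / tr$sd))
    }
    grid <- .propagate(grid, bounds$lower[k], bounds$upper[k], nodes, tr,
                       drift = drift, info_first = info[1])
  }
  if (K == 0L) {
    mu <- drift * sqrt(info[1])
    p_upper[1] <- stats::pnorm(mu - bounds$final_crit)
    p_lower[1] <- 1 - p_upper[1]
  } else {
    tr <- .transition(info[K], info[K + 1], drift)
    p_upper[K + 1] <- sum(grid$w * grid$psi *
                            stats::pnorm((grid$x * tr$r + tr$shift - bounds$final_crit) / tr$sd))
    p_lower[K + 1] <- sum(grid$w * grid$psi *
                            stats::pnorm((bounds$final_crit - grid$x * tr$r - tr$shift) / tr$sd))
  }
  out <- data.frame(
    look = c(as.character(seq_len(K)), "final"),
    info = info,
    lower = c(bounds$lower, NA),
    upper = c(bounds$upper, bounds$final_crit),
    p_lower = p_lower, p_upper = p_upper)
  attr(out, "total_lower") <- sum(p_lower)
  attr(out, "total_upper") <- sum(p_upper)
  out
}

#' @export
print.boundary_set <- function(x, digits = 3, ...) {
  K <- length(x$lower)
  cat("Group sequential boundaries (", K, " interims)\n", sep = "")
  if (K > 0L)
    print(data.frame(look = seq_len(K),
                     info = round(x$info_levels[seq_len(K)], digits),
                     lower = round(x$lower, digits),
                     upper = round(x$upper, digits)))
  cat(sprintf("  final: info = %.*f, critical value = %.*f\n", digits,
              x$info_levels[K + 1], digits, x$final_crit))
  invisible(x)
}
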