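# Design-stage information planning: the expected information I* that
# triggers each interim analysis, computed from the planned number of
# participants with each outcome available and the design-stage covariance
# expectations (sigma*, rho*), assuming 1:1 allocation and monotone
# (staged follow-up) missingness patterns.

#' Planned accrual of outcome data at each interim
#'
#' The number of participants expected to have provided each outcome label
#' at each planned interim analysis, and at the final analysis. Counts must
#' be non-increasing across labels within an interim (staged follow-up:
#' later outcomes are available for fewer participants) and non-decreasing
#' across interims.
#'
#' @param interim_counts numeric matrix (interims by labels) of planned
#'   counts; a vector is taken as a single-label column.
#' @param final_counts planned counts per label at the final analysis.
#' @param labels label names; defaults to the column names.
#' @return An object of class `planned_accrual`: a (K+1)-by-L matrix with
#'   row names `1..K, "final"`.
#' @examples
#' planned_accrual(c(40, 80), 170, labels = "6m")
#' @export
planned_accrual <- function(interim_counts, final_counts, labels = NULL) {
  if (is.vector(interim_counts)) interim_counts <- cbind(interim_counts)
  interim_counts <- as.matrix(interim_counts)
  final_counts <- as.numeric(final_counts)
  if (length(final_counts) != ncol(interim_counts))
    stop("final_counts must have one entry per label")
  m <- rbind(interim_counts, final = final_counts)
  if (is.null(labels)) labels <- colnames(interim_counts)
  if (is.null(labels)) labels <- paste0("s", seq_len(ncol(m)))
  colnames(m) <- labels
  rownames(m) <- c(seq_len(nrow(interim_counts)), "final")
  if (any(m < 0)) stop("planned counts must be non-negative")
  if (ncol(m) > 1L && any(t(apply(m, 1, diff)) > 1e-9))
    stop("within an interim, counts must be non-increasing across labels")
  if (nrow(m) > 1L && any(apply(m, 2, diff) < -1e-9))
    stop("counts must be non-decreasing across interims")
  structure(m, class = c("planned_accrual", "matrix"))
}

# Expected variance of the arm contrast for one set of per-label counts,
# split 1:1 into arms, under monotone patterns and known Sigma.
.expected_variance <- function(counts, S, t_idx) {
  L <- length(counts)
  n_through <- counts - c(counts[-1], 0)  # participants observed up to label j
  A <- matrix(0, L, L)
  for (j in seq_len(L)) {
    if (n_through[j] <= 0) next
    idx <- seq_len(j)
    A[idx, idx] <- A[idx, idx] +
      (n_through[j] / 2) * solve(S[idx, idx, drop = FALSE])
  }
  V <- tryCatch(solve(A), error = function(e)
    stop("expected information is not finite: no planned primary-outcome ",
         "data reachable through the correlation structure"))
  2 * V[t_idx, t_idx]
}

#' Expected information triggering each interim analysis
#'
#' Computes `I*_k = 1 / var(beta)` where the variance is the
#' known-covariance generalized-least-squares variance of the primary-time
#' arm contrast under the planned monotone accrual patterns, 1:1
#' allocation, and the design-stage covariance expectations (typically the
#' protocol sigma* and a common rho* such as 0.5).
#'
#' @param accrual a [planned_accrual()].
#' @param cov a [covariance_model()] with the expected sigma* and rho*,
#'   covering the accrual labels; the *last* label is the primary time.
#' @return Named numeric vector of expected information at each interim and
#'   at the final analysis (`1/PROM-units^2`).
#' @examples
#' acc <- planned_accrual(c(40, 80), 170, labels = "6m")
#' expected_information(acc, covariance_model(c(`6m` = 9), 1))
#' # 0.123, 0.247, 0.525 to 3 dp
#' @export
expected_information <- function(accrual, cov) {
  stopifnot(inherits(accrual, "planned_accrual"),
            inherits(cov, "covariance_model"))
  labels <- colnames(accrual)
  S <- cov_matrix(cov, labels)
  t_idx <- length(labels)
  out <- apply(unclass(accrual), 1, function(counts)
    1 / .expected_variance(counts, S, t_idx))
  stats::setNames(out, rownames(accrual))
}

#' Information fractions of planned interim analyses
#'
#' @param interim_info expected information at each interim, strictly
#'   increasing.
#' @param final_info expected information at the final analysis, above the
#'   last interim value.
#' @return Fractions in (0, 1]; the final fraction is exactly 1.
#' @examples
#' information_fractions(c(0.123, 0.247), 0.525)
#' @export
information_fractions <- function(interim_info, final_info) {
  x <- c(as.numeric(interim_info), as.numeric(final_info))
  if (any(x <= 0) || any(diff(x) <= 0))
    stop("information levels must be positive and strictly increasing")
  x / x[length(x)]
}
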