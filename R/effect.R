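#' Treatment-effect estimate at the primary time
#'
#' Container for the estimated treatment effect on the primary outcome,
#' oriented so that positive values favour the test arm. The standardized
#' statistic and the statistical information follow from the variance:
#' `z = beta / sd(beta)` and `information = 1 / var(beta)`, so that
#' `z = beta * sqrt(information)` holds by construction.
#'
#' @param beta estimated treatment effect (PROM units), oriented.
#' @param variance its variance; must be finite and positive.
#' @param mode `"full"` when early outcomes contributed through the
#'   longitudinal model, `"primary_only"` when only primary-outcome data
#'   were used (the correlation-zeroed analysis).
#' @param group_means optional arm-by-label matrix of estimated means
#'   (unoriented, on the original scale).
#' @param n_per_label optional named counts of observed values per label.
#' @param method optional string recording the estimator used.
#'
#' @return An object of class `effect_estimate` with elements `beta`,
#'   `variance`, `z`, `information`, `mode`, `group_means`, `n_per_label`.
#' @examples
#' effect_estimate(3.31, 1 / 0.325)  # z = 3.31 * sqrt(0.325)
#' @export
effect_estimate <- function(beta, variance,
                            mode = c("full", "primary_only"),
                            group_means = NULL, n_per_label = NULL,
                            method = NULL) {
  mode <- match.arg(mode)
  beta <- unname(as.numeric(beta))
  variance <- unname(as.numeric(variance))
  if (!is.finite(beta)) stop("beta must be finite")
  if (!is.finite(variance) || variance <= 0)
    stop("information undefined: variance must be finite and positive")
  information <- 1 / variance
  structure(
    list(beta = beta, variance = variance, z = beta / sqrt(variance),
         information = information, mode = mode, group_means = group_means,
         n_per_label = n_per_label, method = method),
    class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("Effect estimate (%s): beta = %.*f, se = %.*f, z = %.*f, I = %.*f\n",
              x$mode, digits, x$beta, digits, sqrt(x$variance),
              digits, x$z, digits, x$information))
  invisible(x)
}
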