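#' Per-occasion standard deviations and outcome correlations
#'
#' Bundles the covariance parameters of the longitudinal outcome model: one
#' standard deviation per assessment occasion and a symmetric correlation
#' matrix between occasions. Used both for estimated covariance (hats) and
#' for design-stage expectations (the starred sigma* and rho* values used to
#' plan interim analyses).
#'
#' @param sigmas named numeric vector of per-label standard deviations
#'   (PROM units), all positive; names are the schedule labels.
#' @param correlations symmetric correlation matrix with unit diagonal and
#'   entries in `[-1, 1]`, with dimnames equal to `names(sigmas)` (a scalar
#'   correlation may be given and is applied to all pairs).
#' @param repair if `TRUE` (default) a non-positive-definite matrix is
#'   repaired by clipping its eigenvalues (see [repair_correlation()]), with
#'   a warning; if `FALSE` it is an error.
#'
#' @return An object of class `covariance_model`.
#' @examples
#' covariance_model(c(`3m` = 20, `6m` = 24), 0.65)
#' @export
covariance_model <- function(sigmas, correlations, repair = TRUE) {
  if (is.null(names(sigmas)) && length(sigmas) == 1L) names(sigmas) <- "t"
  if (is.null(names(sigmas))) stop("sigmas must be named by label")
  if (any(!is.finite(sigmas)) || any(sigmas <= 0))
    stop("all sigmas must be finite and positive")
  L <- length(sigmas)
  if (length(correlations) == 1L && !is.matrix(correlations)) {
    rho <- as.numeric(correlations)
    correlations <- matrix(rho, L, L)
    diag(correlations) <- 1
  }
  correlations <- as.matrix(correlations)
  if (!all(dim(correlations) == L))
    stop("correlation matrix dimension does not match sigmas")
  dimnames(correlations) <- list(names(sigmas), names(sigmas))
  if (max(abs(correlations - t(correlations))) > 1e-10)
    stop("correlation matrix must be symmetric")
  correlations <- (correlations + t(correlations)) / 2
  if (any(abs(correlations) > 1 + 1e-10)) stop("|rho| must be <= 1")
  if (max(abs(diag(correlations) - 1)) > 1e-10)
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 && L > 1L) {
    if (!repair) stop("correlation matrix is not positive definite")
    warning("correlation matrix not positive definite; eigenvalue-clipped repair applied")
    correlations <- repair_correlation(correlations)
  }
  structure(list(sigmas = sigmas, correlations = correlations),
            class = "covariance_model")
}

#' Repair a correlation matrix to positive definiteness
#'
#' Clips eigenvalues below `eps`, reconstructs, and rescales to unit
#' diagonal. A minimal repair for nearly-singular estimated correlation
#' matrices.
#'
#' @param mat symmetric matrix with unit diagonal.
#' @param eps smallest retained eigenvalue (default `1e-8`).
#' @return A positive-definite correlation matrix.
#' @export
repair_correlation <- function(mat, eps = 1e-8) {
  e <- eigen((mat + t(mat)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  m <- e$vectors %*% (vals * t(e$vectors))
  d <- 1 / sqrt(diag(m))
  m <- m * tcrossprod(d)
  diag(m) <- 1
  dimnames(m) <- dimnames(mat)
  m
}

#' Covariance matrix implied by a covariance model
#'
#' @param cov a [covariance_model()].
#' @param labels labels to extract, in order (default all).
#' @return The covariance matrix `diag(sigma) %*% R %*% diag(sigma)`.
#' @export
cov_matrix <- function(cov, labels = names(cov$sigmas)) {
  stopifnot(inherits(cov, "covariance_model"))
  if (!all(labels %in% names(cov$sigmas)))
    stop("covariance model does not cover labels: ",
         paste(setdiff(labels, names(cov$sigmas)), collapse = ", "))
  s <- cov$sigmas[labels]
  R <- cov$correlations[labels, labels, drop = FALSE]
  S <- R * tcrossprod(s)
  dimnames(S) <- list(labels, labels)
  S
}

#' @export
print.covariance_model <- function(x, digits = 3, ...) {
  cat("Covariance model\n  sigmas:\n")
  print(round(x$sigmas, digits))
  if (length(x$sigmas) > 1L) {
    cat("  correlations:\n")
    print(round(x$correlations, digits))
  }
  invisible(x)
}
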