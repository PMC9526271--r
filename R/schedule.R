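#' Define an outcome assessment schedule
#'
#' An outcome schedule names the occasions at which a patient-reported
#' outcome measure (PROM) is collected, their nominal offsets (in days) from
#' randomization, and which occasion is the primary endpoint. Occasions
#' collected *after* the primary time (late outcomes, e.g. a 12-month score
#' when the 6-month score is primary) may be listed; they are retained in
#' datasets but excluded from the longitudinal model, whose last modelled
#' occasion is always the primary one.
#'
#' @param labels character vector of unique assessment-time names, ordered
#'   by time (e.g. `c("6w", "3m", "6m", "12m")`).
#' @param offsets_days numeric vector of nominal days post-randomization for
#'   each label; strictly increasing.
#' @param primary_label the label of the primary (final) outcome.
#' @param direction `"higher_better"` if larger PROM values indicate better
#'   outcomes (e.g. Oxford scores), `"lower_better"` otherwise (e.g.
#'   disability indices). Treatment effects are oriented so that positive
#'   values favour the test arm.
#'
#' @return An object of class `outcome_schedule`.
#' @examples
#' outcome_schedule(c("3m", "6m", "12m"), c(91, 183, 365), "12m",
#'                  direction = "lower_better")
#' @export
outcome_schedule <- function(labels, offsets_days, primary_label,
                             direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  labels <- as.character(labels)
  offsets_days <- as.numeric(offsets_days)
  if (anyDuplicated(labels)) stop("schedule labels must be unique")
  if (length(labels) != length(offsets_days))
    stop("labels and offsets_days must have the same length")
  if (length(labels) < 1L) stop("at least one assessment label is required")
  if (any(!is.finite(offsets_days)) || any(diff(offsets_days) <= 0))
    stop("offsets_days must be finite and strictly increasing")
  if (!primary_label %in% labels)
    stop("primary_label '", primary_label, "' is not among the labels")
  names(offsets_days) <- labels
  structure(
    list(labels = labels, offsets_days = offsets_days,
         primary_label = primary_label, direction = direction),
    class = "outcome_schedule")
}

#' Labels entering the longitudinal model
#'
#' Returns the schedule labels at or before the primary time; outcomes
#' collected later than the primary endpoint are excluded from modelling.
#'
#' @param schedule an [outcome_schedule()].
#' @return character vector of modelled labels, ending with the primary.
#' @export
modelled_labels <- function(schedule) {
  stopifnot(inherits(schedule, "outcome_schedule"))
  keep <- schedule$offsets_days <= schedule$offsets_days[schedule$primary_label]
  schedule$labels[keep]
}

#' @export
print.outcome_schedule <- function(x, ...) {
  cat("Outcome schedule (", x$direction, ")\n", sep = "")
  mark <- ifelse(x$labels == x$primary_label, " [primary]",
                 ifelse(x$labels %in% modelled_labels(x), "", " [late]"))
  cat(paste0("  ", format(x$labels), "  day ",
             format(x$offsets_days), mark, collapse = "\n"), "\n")
  invisible(x)
}
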