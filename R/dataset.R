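#' Dated longitudinal records for a two-arm trial
#'
#' Stores one row per *observed* assessment (missing assessments are simply
#' absent) together with the outcome schedule and the participant register
#' (id, arm, randomization date). The register matters for calendar replay:
#' a participant randomized but not yet assessed still counts as recruited.
#'
#' @param records data frame with columns `participant_id`, `arm`
#'   (`"control"`/`"test"`), `randomization_date` (`Date`), `time_label`,
#'   `assessment_date` (`Date`), `value` (finite numeric).
#' @param schedule an [outcome_schedule()]; all `time_label` values must be
#'   schedule labels.
#' @param participants optional data frame (`participant_id`, `arm`,
#'   `randomization_date`), one row per randomized participant; derived
#'   from `records` when omitted (participants without any observed
#'   assessment are then unknown).
#'
#' @return An object of class `longitudinal_dataset`.
#' @export
longitudinal_dataset <- function(records, schedule, participants = NULL) {
  stopifnot(inherits(schedule, "outcome_schedule"))
  req <- c("participant_id", "arm", "randomization_date", "time_label",
           "assessment_date", "value")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  records <- as.data.frame(records)[req]
  records$participant_id <- as.character(records$participant_id)
  records$arm <- as.character(records$arm)
  records$time_label <- as.character(records$time_label)
  records$randomization_date <- as.Date(records$randomization_date)
  records$assessment_date <- as.Date(records$assessment_date)
  records$value <- as.numeric(records$value)
  if (!all(records$arm %in% c("control", "test")))
    stop("arm must be 'control' or 'test'")
  if (!all(records$time_label %in% schedule$labels))
    stop("unknown time_label values: ",
         paste(setdiff(records$time_label, schedule$labels), collapse = ", "))
  if (any(!is.finite(records$value))) stop("outcome values must be finite")
  if (any(records$assessment_date < records$randomization_date))
    stop("assessment_date must not precede randomization_date")
  if (anyDuplicated(records[c("participant_id", "time_label")]))
    stop("a participant may appear at most once per time label")
  if (is.null(participants)) {
    participants <- unique(records[c("participant_id", "arm",
                                     "randomization_date")])
  } else {
    participants <- as.data.frame(participants)[
      c("participant_id", "arm", "randomization_date")]
    participants$participant_id <- as.character(participants$participant_id)
    participants$arm <- as.character(participants$arm)
    participants$randomization_date <- as.Date(participants$randomization_date)
    if (anyDuplicated(participants$participant_id))
      stop("duplicated participant ids in register")
    if (!all(records$participant_id %in% participants$participant_id))
      stop("records contain participants absent from the register")
  }
  if (anyDuplicated(participants$participant_id))
    stop("participants with inconsistent arm/randomization information")
  if (!all(c("control", "test") %in% participants$arm))
    stop("both a control and a test arm are required")
  rownames(records) <- NULL
  rownames(participants) <- NULL
  structure(list(records = records, schedule = schedule,
                 participants = participants),
            class = "longitudinal_dataset")
}

#' Observed sample size per assessment label
#'
#' @param data a [longitudinal_dataset()].
#' @param by_arm if `TRUE`, a labels-by-arm matrix of counts.
#' @return Named integer vector (or matrix) of observed counts per label.
#' @export
n_per_label <- function(data, by_arm = FALSE) {
  stopifnot(inherits(data, "longitudinal_dataset"))
  labs <- data$schedule$labels
  if (by_arm) {
    tab <- table(factor(data$records$time_label, levels = labs),
                 factor(data$records$arm, levels = c("control", "test")))
    return(unclass(tab))
  }
  n <- table(factor(data$records$time_label, levels = labs))
  stats::setNames(as.integer(n), labs)
}

#' Read or write a trial as a long-format CSV
#'
#' The on-disk interchange format is one row per observed assessment with
#' columns `participant_id, arm, randomization_date, time_label,
#' assessment_date, value` and ISO-8601 dates. Participants with no
#' observed assessment cannot be represented in this format and are lost on
#' a write/read round trip.
#'
#' @param path file path.
#' @param schedule the [outcome_schedule()] the file refers to.
#' @return `read_trial_csv()` returns a [longitudinal_dataset()];
#'   `write_trial_csv()` returns `path`, invisibly.
#' @export
read_trial_csv <- function(path, schedule) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  longitudinal_dataset(df, schedule)
}

#' @rdname read_trial_csv
#' @param data a [longitudinal_dataset()] to write.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "longitudinal_dataset"))
  df <- data$records
  ord <- order(df$randomization_date, df$participant_id,
               match(df$time_label, data$schedule$labels))
  df <- df[ord, , drop = FALSE]
  df$randomization_date <- format(df$randomization_date, "%Y-%m-%d")
  df$assessment_date <- format(df$assessment_date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  n <- nrow(x$participants)
  cat("Longitudinal trial dataset: ", n, " participants (",
      sum(x$participants$arm == "control"), " control / ",
      sum(x$participants$arm == "test"), " test), ",
      nrow(x$records), " observed assessments\n", sep = "")
  cat("  randomized ", format(min(x$participants$randomization_date)), " to ",
      format(max(x$participants$randomization_date)), "\n", sep = "")
  cat("  observed per label: ",
      paste(names(n_per_label(x)), n_per_label(x), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
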