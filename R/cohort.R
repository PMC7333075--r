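#' Cohort records and sample-derivation filters
#'
#' A cohort table has one row per enrolled driver applicant with the columns
#' `drive_id`, `ore_score` (non-negative integer on-road-exam infraction
#' score), and the workflow-completion flags `completed_practice`,
#' `completed_comprehension`, `completed_assessment`, `replay_uploaded`.
#'
#' @param drive_id character vector of identifiers.
#' @param ore_score non-negative integer scores.
#' @param completed_practice,completed_comprehension,completed_assessment,replay_uploaded
#'   logical completion flags (recycled, default `TRUE`).
#' @return a data.frame with class `cohort_table`.
#' @export
cohort_table <- function(drive_id, ore_score,
                         completed_practice = TRUE,
                         completed_comprehension = TRUE,
                         completed_assessment = TRUE,
                         replay_uploaded = TRUE) {
  ore_score <- as.integer(ore_score)
  if (any(is.na(ore_score)) || any(ore_score < 0))
    stop("ore_score must be a non-negative integer")
  out <- data.frame(drive_id = as.character(drive_id),
                    ore_score = ore_score,
                    completed_practice = rep_len(completed_practice, length(drive_id)),
                    completed_comprehension = rep_len(completed_comprehension, length(drive_id)),
                    completed_assessment = rep_len(completed_assessment, length(drive_id)),
                    replay_uploaded = rep_len(replay_uploaded, length(drive_id)))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Read / write a cohort CSV
#'
#' Header: `drive_id,ore_score,completed_practice,completed_comprehension,
#' completed_assessment,replay_uploaded`.
#'
#' @param path CSV file path.
#' @return for `read_cohort`, a `cohort_table`.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cohort_table(df$drive_id, df$ore_score,
               as.logical(df$completed_practice),
               as.logical(df$completed_comprehension),
               as.logical(df$completed_assessment),
               as.logical(df$replay_uploaded))
}

#' @rdname read_cohort
#' @param cohort a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the sample-derivation exclusion filters
#'
#' A record enters the analyzable sample iff every workflow stage was
#' completed and the replay uploaded. Each excluded record is tallied under
#' exactly one reason, checked in workflow order: practice drive ->
#' comprehension test -> assessment drive -> replay upload.
#'
#' @param cohort a `cohort_table` (or data.frame with the same columns).
#' @return list with `analyzable` (the retained `cohort_table`) and
#'   `exclusion_tally` (named integer vector: `incomplete_practice`,
#'   `incomplete_comprehension`, `incomplete_assessment`, `missing_replay`).
#' @export
#' @examples
#' co <- cohort_table(c("a", "b"), c(0, 30), completed_practice = c(TRUE, FALSE))
#' apply_sample_filters(co)$exclusion_tally
apply_sample_filters <- function(cohort) {
  reasons <- c("incomplete_practice", "incomplete_comprehension",
               "incomplete_assessment", "missing_replay")
  reason <- rep(NA_character_, nrow(cohort))
  reason[!cohort$replay_uploaded]          <- reasons[4]
  reason[!cohort$completed_assessment]     <- reasons[3]
  reason[!cohort$completed_comprehension]  <- reasons[2]
  reason[!cohort$completed_practice]       <- reasons[1]
  tally <- vapply(reasons, function(r) sum(reason %in% r, na.rm = TRUE), 0L)
  keep <- is.na(reason)
  analyzable <- cohort[keep, , drop = FALSE]
  rownames(analyzable) <- NULL
  list(analyzable = analyzable, exclusion_tally = tally)
}
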