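#' Cohort tables
#'
#' A cohort is an ordinary tibble with one row per patient and the columns
#' below. All estimation functions in the package validate their cohort
#' input with [validate_cohort()] before computing.
#'
#' \describe{
#'   \item{patient_id}{character, unique within the cohort}
#'   \item{sex}{`"male"` or `"female"`}
#'   \item{site}{index-VTE site: `"distal_dvt"`, `"proximal_dvt"` or
#'     `"pulmonary_embolism"`}
#'   \item{ddimer_ng_ml}{D-dimer in ng/mL, strictly positive}
#'   \item{time_months}{follow-up since anticoagulation discontinuation,
#'     months, non-negative}
#'   \item{event}{`"recurrence"` or `"censored"`}
#'   \item{end_reason}{why follow-up ended: `"recurrence"`,
#'     `"completed_24mo"`, `"restarted_anticoagulation"`, `"death_other"`,
#'     `"withdrew"` or `"lost"`}
#'   \item{excluded_before_assessment}{optional; `"none"` for assessed
#'     patients, otherwise the pre-assessment exit reason
#'     (`"early_recurrence"`, `"other_indication"`, `"withdrew_consent"`,
#'     `"cancer"`)}
#' }
#'
#' @name cohort-format
NULL

cohort_required_cols <- c("patient_id", "sex", "site", "ddimer_ng_ml",
                          "time_months", "event", "end_reason")

cohort_levels <- list(
  sex = c("male", "female"),
  site = c("distal_dvt", "proximal_dvt", "pulmonary_embolism"),
  event = c("recurrence", "censored"),
  end_reason = c("recurrence", "completed_24mo", "restarted_anticoagulation",
                 "death_other", "withdrew", "lost"),
  excluded_before_assessment = c("none", "early_recurrence",
                                 "other_indication", "withdrew_consent",
                                 "cancer")
)

#' Validate a cohort table
#'
#' Checks the cohort schema (see [cohort-format]) and its invariants:
#' positive D-dimer, non-negative follow-up time, recurrence events carrying
#' `end_reason == "recurrence"`, and unique patient ids. Categorical values
#' are normalised to lower case.
#'
#' @param cohort A data frame in the [cohort-format].
#' @param require_nonempty Error on a zero-row cohort (the default for all
#'   estimation functions).
#' @return The validated cohort as a tibble, invisibly usable in pipes.
#' @export
validate_cohort <- function(cohort, require_nonempty = TRUE) {
  if (!is.data.frame(cohort)) abort("`cohort` must be a data frame")
  names(cohort) <- tolower(names(cohort))
  missing_cols <- setdiff(cohort_required_cols, names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  cohort <- tibble::as_tibble(cohort)
  if (!"excluded_before_assessment" %in% names(cohort)) {
    cohort$excluded_before_assessment <- "none"
  }
  cohort <- dplyr::mutate(
    cohort,
    patient_id = as.character(.data$patient_id),
    dplyr::across(c("sex", "site", "event", "end_reason",
                    "excluded_before_assessment"),
                  ~ tolower(as.character(.x))),
    ddimer_ng_ml = as.numeric(.data$ddimer_ng_ml),
    time_months = as.numeric(.data$time_months)
  )
  if (nrow(cohort) == 0) {
    if (require_nonempty) abort("cohort has no rows")
    return(cohort)
  }
  for (col in names(cohort_levels)) {
    bad <- !cohort[[col]] %in% cohort_levels[[col]] & !is.na(cohort[[col]])
    if (any(bad)) {
      abort(sprintf("invalid %s value(s) %s (patient_id %s)", col,
                    paste(unique(cohort[[col]][bad]), collapse = ", "),
                    paste(utils::head(cohort$patient_id[bad], 5), collapse = ", ")))
    }
  }
  bad_dd <- is.na(cohort$ddimer_ng_ml) | cohort$ddimer_ng_ml <= 0
  if (any(bad_dd)) {
    abort(sprintf("D-dimer must be > 0 ng/mL; offending patient_id: %s",
                  paste(utils::head(cohort$patient_id[bad_dd], 5), collapse = ", ")))
  }
  bad_t <- is.na(cohort$time_months) | cohort$time_months < 0
  if (any(bad_t)) {
    abort(sprintf("follow-up time must be >= 0 months; offending patient_id: %s",
                  paste(utils::head(cohort$patient_id[bad_t], 5), collapse = ", ")))
  }
  bad_ev <- cohort$event == "recurrence" & cohort$end_reason != "recurrence"
  if (any(bad_ev)) {
    abort(sprintf(
      "event = recurrence requires end_reason = recurrence; offending patient_id: %s",
      paste(utils::head(cohort$patient_id[bad_ev], 5), collapse = ", ")))
  }
  if (anyDuplicated(cohort$patient_id)) {
    abort("patient_id values must be unique within a cohort")
  }
  cohort
}

# 0/1 event indicator used by every survival routine
event_indicator <- function(cohort) as.integer(cohort$event == "recurrence")

#' Read a cohort file
#'
#' Reads a delimited cohort table (comma by default, tab accepted — the
#' delimiter is sniffed from the header line), validates it against the
#' [cohort-format] schema and returns a tibble with rows in file order.
#' Header names are matched case-insensitively.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; `NULL` (default) sniffs `,` vs tab.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_cohort(raw, require_nonempty = FALSE)
}

#' Write a cohort file
#'
#' Writes a cohort losslessly as delimited text readable by [read_cohort()].
#'
#' @param cohort A cohort tibble (validated before writing).
#' @param path Output path.
#' @param delim Field delimiter, `,` (default) or tab.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  cohort <- validate_cohort(cohort, require_nonempty = FALSE)
  readr::write_delim(cohort, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Patient-flow accounting
#'
#' Reproduces enrolment-to-assessment flow accounting: how many enrolled
#' patients exited before the risk assessment (and why), how many were
#' assessed, and the split into high- and low-risk strata with percentages
#' of assessed patients (rounded half-up to integers).
#'
#' @param cohort Enrolled cohort; pre-assessment exits carry a non-`"none"`
#'   `excluded_before_assessment` flag.
#' @param risk_class Per-patient risk label, `"high"`/`"low"`, `NA` for
#'   excluded patients. Defaults to a `risk_class` column of `cohort` (as
#'   added by [vpm_score()]).
#' @return A `vpm_flow_summary` list; see [tidy.vpm_flow_summary()].
#' @export
flow_summary <- function(cohort, risk_class = NULL) {
  cohort <- validate_cohort(cohort)
  if (is.null(risk_class)) {
    if (!"risk_class" %in% names(cohort)) {
      abort("supply `risk_class` or a cohort with a risk_class column")
    }
    risk_class <- cohort$risk_class
  }
  risk_class <- tolower(as.character(risk_class))
  if (length(risk_class) != nrow(cohort)) {
    abort("`risk_class` must have one entry per patient")
  }
  excluded <- cohort$excluded_before_assessment != "none"
  if (any(excluded & !is.na(risk_class))) {
    abort("patients excluded before assessment cannot carry a risk label")
  }
  if (any(!excluded & is.na(risk_class))) {
    abort("every assessed patient needs a risk label")
  }
  n_enrolled <- nrow(cohort)
  n_excluded <- sum(excluded)
  n_assessed <- n_enrolled - n_excluded
  if (n_assessed == 0) abort("no assessed patients: all enrolled were excluded")
  bad <- setdiff(unique(risk_class[!excluded]), c("high", "low"))
  if (length(bad) > 0) abort("risk labels must be 'high' or 'low'")
  n_high <- sum(risk_class[!excluded] == "high")
  n_low <- n_assessed - n_high
  reasons <- cohort$excluded_before_assessment[excluded]
  structure(list(
    n_enrolled = n_enrolled,
    n_exited_before_assessment = n_excluded,
    exits_by_reason = table(factor(reasons,
      levels = setdiff(cohort_levels$excluded_before_assessment, "none"))),
    n_assessed = n_assessed,
    n_high_risk = n_high,
    n_low_risk = n_low,
    pct_high_risk = pct_of(n_high, n_assessed),
    pct_low_risk = pct_of(n_low, n_assessed)
  ), class = "vpm_flow_summary")
}

#' @export
print.vpm_flow_summary <- function(x, ...) {
  cat(sprintf("Patient flow: %d enrolled, %d exited before assessment, %d assessed\n",
              x$n_enrolled, x$n_exited_before_assessment, x$n_assessed))
  if (x$n_exited_before_assessment > 0) {
    nz <- x$exits_by_reason[x$exits_by_reason > 0]
    cat("  pre-assessment exits:",
        paste(sprintf("%s %d", names(nz), nz), collapse = ", "), "\n")
  }
  cat(sprintf("  high risk: %d (%d%%)   low risk: %d (%d%%)\n",
              x$n_high_risk, x$pct_high_risk, x$n_low_risk, x$pct_low_risk))
  invisible(x)
}

#' Tidy a flow summary
#'
#' @param x A `vpm_flow_summary` from [flow_summary()].
#' @param ... Unused.
#' @return One row per flow node with count and percentage of assessed
#'   patients where applicable.
#' @export
tidy.vpm_flow_summary <- function(x, ...) {
  tibble::tibble(
    node = c("enrolled", "exited_before_assessment", "assessed",
             "high_risk", "low_risk"),
    n = c(x$n_enrolled, x$n_exited_before_assessment, x$n_assessed,
          x$n_high_risk, x$n_low_risk),
    pct_of_assessed = c(NA, NA, NA, x$pct_high_risk, x$pct_low_risk)
  )
}
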