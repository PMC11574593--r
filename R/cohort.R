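#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats quantile rbinom rlnorm rmultinom rpois runif setNames
NULL

# Flag groups used throughout the rule engine and adjudicator.
special_flags <- c(
  "pregnant", "pre_endourological_procedure", "renal_transplant_within_60_days"
)
localized_symptoms <- c(
  "urgency", "frequency", "dysuria", "suprapubic_pain",
  "pelvic_discomfort", "flank_pain"
)
systemic_signs <- c("fever", "clinical_instability", "acute_mental_status_change")

urinalysis_markers <- c("leukocyturia", "bacteria_seen", "nitrites_positive")

non_urinary_sources <- c(
  "pneumonia", "intra_abdominal", "osteomyelitis_decubitus",
  "covid19", "cellulitis", "epididymitis"
)

#' Column dictionary of a cohort tibble
#'
#' A cohort is a tibble with one row per antibiotic-treated suspected-UTI
#' case. Flag columns are logicals; `alternate_explanation_for_systemic` is a
#' character label (`NA` when no non-urinary cause for systemic signs is
#' documented); `courses` is a list-column of tibbles with columns
#' `agent_class` (character) and `days_of_therapy` (positive integer);
#' `documented_non_urinary_source` is `"none"` or one of the recognised
#' source labels; `truly_needed` is the full-stay reference standard.
#'
#' @return A character vector of the canonical column names, in order.
#' @export
cohort_columns <- function() {
  c(
    "record_id", "age_years", "sex",
    special_flags,
    localized_symptoms,
    systemic_signs,
    "alternate_explanation_for_systemic", "poor_historian",
    "ua_available", urinalysis_markers, "leukocyte_count",
    "courses",
    "documented_non_urinary_source", "truly_needed", "notes"
  )
}

#' Build a single patient record
#'
#' Convenience constructor returning a one-row cohort tibble with every flag
#' defaulted to `FALSE`, no antibiotic courses, and `truly_needed = FALSE`.
#' Useful for tests and worked examples; bind rows of these to build a toy
#' cohort.
#'
#' @param record_id Unique record identifier.
#' @param age_years Age in years (positive real).
#' @param sex `"female"` or `"male"`.
#' @param courses A tibble with columns `agent_class` and `days_of_therapy`,
#'   or `NULL` for no courses.
#' @param ... Named overrides for any other cohort column, e.g.
#'   `dysuria = TRUE`.
#' @return A one-row validated cohort tibble.
#' @examples
#' uti_record("A1", dysuria = TRUE)
#' @export
uti_record <- function(record_id = "R001", age_years = 64, sex = "female",
                       courses = NULL, ...) {
  rec <- tibble::tibble(
    record_id = as.character(record_id),
    age_years = as.numeric(age_years),
    sex = as.character(sex)
  )
  for (f in c(special_flags, localized_symptoms, systemic_signs)) rec[[f]] <- FALSE
  rec$alternate_explanation_for_systemic <- NA_character_
  rec$poor_historian <- FALSE
  rec$ua_available <- FALSE
  for (m in urinalysis_markers) rec[[m]] <- NA
  rec$leukocyte_count <- NA_real_
  rec$courses <- list(courses %||% empty_courses())
  rec$documented_non_urinary_source <- "none"
  rec$truly_needed <- FALSE
  rec$notes <- NA_character_
  dots <- list(...)
  bad <- setdiff(names(dots), cohort_columns())
  if (length(bad) > 0) {
    abort(paste0("Unknown cohort field(s): ", paste(bad, collapse = ", ")))
  }
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  validate_cohort(rec)
}

empty_courses <- function() {
  tibble::tibble(agent_class = character(), days_of_therapy = integer())
}

#' Validate a cohort tibble
#'
#' Checks the structural invariants of a cohort: canonical columns present,
#' unique record ids, positive ages, explicit (non-missing) special-population
#' and symptom flags, no alternate explanation without a systemic sign, no
#' urinalysis values when `ua_available` is `FALSE`, non-negative leukocyte
#' counts, and positive integer days of therapy. Raises an error naming the
#' offending record and field on the first violation.
#'
#' @param cohort A cohort tibble (see [cohort_columns()]).
#' @return The cohort, invisibly coerced to a tibble, with columns in
#'   canonical order.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  cohort <- cohort[, cohort_columns()]
  if (nrow(cohort) == 0) return(cohort)

  if (anyNA(cohort$record_id)) abort("record_id must not be missing")
  dup <- cohort$record_id[duplicated(cohort$record_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate record_id: ", paste(unique(dup), collapse = ", ")))
  }
  check_field <- function(ok, field) {
    if (all(ok)) return(invisible())
    abort(paste0(
      "Invalid ", field, " in record(s): ",
      paste(utils::head(cohort$record_id[!ok], 5), collapse = ", ")
    ))
  }
  check_field(!is.na(cohort$age_years) & cohort$age_years > 0, "age_years")
  check_field(cohort$sex %in% c("female", "male"), "sex")
  for (f in c(special_flags, localized_symptoms, systemic_signs, "poor_historian",
              "ua_available")) {
    check_field(is.logical(cohort[[f]]) & !is.na(cohort[[f]]), f)
  }
  systemic_any <- Reduce(`|`, cohort[systemic_signs])
  check_field(
    systemic_any | is.na(cohort$alternate_explanation_for_systemic),
    "alternate_explanation_for_systemic (present without any systemic sign)"
  )
  ua_absent_ok <- cohort$ua_available |
    (is.na(cohort$leukocyturia) & is.na(cohort$bacteria_seen) &
       is.na(cohort$nitrites_positive) & is.na(cohort$leukocyte_count))
  check_field(ua_absent_ok, "urinalysis fields (values present while ua_available is FALSE)")
  check_field(is.na(cohort$leukocyte_count) | cohort$leukocyte_count >= 0,
              "leukocyte_count")
  check_field(cohort$documented_non_urinary_source %in% c("none", non_urinary_sources),
              "documented_non_urinary_source")
  courses_ok <- vapply(cohort$courses, function(cr) {
    is.data.frame(cr) &&
      all(c("agent_class", "days_of_therapy") %in% names(cr)) &&
      (nrow(cr) == 0 ||
         (all(!is.na(cr$agent_class)) &&
            all(cr$days_of_therapy >= 1) &&
            all(cr$days_of_therapy == round(cr$days_of_therapy)) &&
            !anyDuplicated(cr$agent_class)))
  }, logical(1))
  check_field(courses_ok, "courses (need unique agent_class, integer days_of_therapy >= 1)")
  cohort
}

#' Apply the study eligibility filter
#'
#' Retains hospitalized adults: age at least 18 years, admitted (not
#' discharged from the emergency department), not on 24-hour observation, and
#' not a one-time order. Admission metadata may be supplied as a separate
#' tibble keyed by `record_id` with logical columns `admitted`,
#' `observation_only` and `onetime_order`, or carried as columns of the
#' cohort itself; if absent entirely, all records are assumed admitted
#' inpatients and only the age criterion applies. The filter is total (never
#' errors) and idempotent, and the count of records removed for each reason
#' is attached as the `"exclusions"` attribute and reported via a message.
#'
#' @param cohort A cohort tibble.
#' @param metadata Optional tibble with columns `record_id`, `admitted`,
#'   `observation_only`, `onetime_order`.
#' @return The filtered cohort, original order preserved.
#' @export
apply_eligibility <- function(cohort, metadata = NULL) {
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  meta_cols <- c("admitted", "observation_only", "onetime_order")
  if (!is.null(metadata)) {
    idx <- match(cohort$record_id, metadata$record_id)
    if (anyNA(idx)) abort("metadata missing rows for some record_id values")
    meta <- metadata[idx, , drop = FALSE]
  } else if (all(meta_cols %in% names(cohort))) {
    meta <- cohort
  } else {
    meta <- tibble::tibble(
      admitted = rep(TRUE, n),
      observation_only = rep(FALSE, n),
      onetime_order = rep(FALSE, n)
    )
  }
  underage <- cohort$age_years < 18
  not_admitted <- !underage & !meta$admitted
  observation <- !underage & meta$admitted & meta$observation_only
  onetime <- !underage & meta$admitted & !meta$observation_only & meta$onetime_order
  drop <- underage | not_admitted | observation | onetime
  exclusions <- c(
    under_18 = sum(underage),
    ed_discharge = sum(not_admitted),
    observation_only = sum(observation),
    onetime_order = sum(onetime)
  )
  if (any(drop)) {
    inform(paste0(
      "Eligibility filter removed ", sum(drop), " of ", n, " record(s): ",
      paste(names(exclusions), exclusions, sep = "=", collapse = ", ")
    ))
  }
  out <- cohort[!drop, , drop = FALSE]
  attr(out, "exclusions") <- exclusions
  out
}
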