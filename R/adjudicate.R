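#' Adjudicate clinical syndromes and the treatment reference standard
#'
#' Classifies every record into one of four syndromes, using full-stay
#' information, with the precedence other infection > pyelonephritis >
#' cystitis > ASB:
#'
#' * **other_infection** — a non-urinary source of infection is documented
#'   (pneumonia, intra-abdominal, osteomyelitis/decubitus, COVID-19,
#'   cellulitis, epididymitis). Resolved first because the pyelonephritis
#'   definition requires the absence of another etiology. A concurrent true
#'   UTI (e.g. a urinary pathogen later found in blood and urine) keeps this
#'   label; the reference standard, not the syndrome, records the true need.
#' * **pyelonephritis** — flank pain, or fever/clinical instability without
#'   an alternate explanation.
#' * **cystitis** — localized urinary symptoms (dysuria in the narrow
#'   definition; any localized symptom here, matching the rule's Question 2
#'   list) without fever.
#' * **asb** — the all-negative residual: no documented urinary symptoms and
#'   no fever or clinical instability attributable to the urinary tract
#'   (systemic signs carrying an alternate explanation still classify as
#'   ASB).
#'
#' `asb_with_treatment_indication` marks ASB records with a guideline
#' treatment indication (pregnancy, impending endourological procedure,
#' recent renal transplant). `truly_needed` passes through the adjudicated
#' reference standard (see [cdst_true_need()]). `inappropriate` flags
#' treatment without documented evidence of urinary symptoms or a specific
#' ASB treatment indication: ASB without an indication, no documented
#' non-urinary source, and no true need on full-stay review.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `record_id`, `syndrome`,
#'   `asb_with_treatment_indication`, `truly_needed`, `inappropriate`.
#' @examples
#' cdst_adjudicate(uti_record("A", dysuria = TRUE, truly_needed = TRUE))
#' @export
cdst_adjudicate <- function(cohort) {
  cohort <- validate_cohort(cohort)
  truths <- cdst_true_need(cohort)
  special_any <- Reduce(`|`, cohort[special_flags])
  localized_any <- Reduce(`|`, cohort[localized_symptoms])
  alt_absent <- is.na(cohort$alternate_explanation_for_systemic)

  syndrome <- dplyr::case_when(
    cohort$documented_non_urinary_source != "none" ~ "other_infection",
    cohort$flank_pain |
      ((cohort$fever | cohort$clinical_instability) & alt_absent) ~ "pyelonephritis",
    localized_any & !cohort$fever ~ "cystitis",
    .default = "asb"
  )
  tibble::tibble(
    record_id = cohort$record_id,
    syndrome = syndrome,
    asb_with_treatment_indication = syndrome == "asb" & special_any,
    truly_needed = truths$truly_needed,
    inappropriate = syndrome == "asb" & !special_any &
      cohort$documented_non_urinary_source == "none" & !truths$truly_needed
  )
}

#' Extract the adjudicated reference standard
#'
#' Returns the full-stay chart-review determination of whether treatment for
#' a urinary pathogen was truly needed, unchanged. The reference standard is
#' an input field (human adjudication), never computed; this accessor exists
#' so the accuracy module is decoupled from the record schema. Errors if any
#' record lacks the adjudication, since every record used in accuracy
#' evaluation must carry it.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `record_id` and `truly_needed`.
#' @export
cdst_true_need <- function(cohort) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) > 0 && anyNA(cohort$truly_needed)) {
    abort(paste0(
      "Missing adjudicated truly_needed in record(s): ",
      paste(utils::head(cohort$record_id[is.na(cohort$truly_needed)], 5),
            collapse = ", ")
    ))
  }
  tibble::tibble(record_id = cohort$record_id,
                 truly_needed = as.logical(cohort$truly_needed))
}

#' Count syndromes in an adjudicated cohort
#'
#' @param labels Output of [cdst_adjudicate()].
#' @return A tibble with `syndrome`, `n`, and `percent` (share of all
#'   records, half-up rounded to one decimal).
#' @export
syndrome_counts <- function(labels) {
  labels |>
    dplyr::count(.data$syndrome, name = "n") |>
    dplyr::mutate(percent = round_half_up(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}
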