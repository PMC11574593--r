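#' Evaluate the 3-question decision-support rule
#'
#' Applies the sequential 3-question rule to every record of a cohort, using
#' only information available at decision time (adjudication fields are never
#' read):
#'
#' * **Q1 — special populations.** Is the patient pregnant, is the culture
#'   requested before an endourological procedure, or was there a renal
#'   transplant within the past 60 days? Any of these justifies testing and
#'   treating bacteriuria regardless of symptoms.
#' * **Q2 — localized urinary symptoms.** Urgency, frequency, dysuria,
#'   suprapubic pain, pelvic discomfort, or flank pain. Any one makes urine
#'   studies and treatment appropriate.
#' * **Q3 — systemic signs.** Fever, clinical instability, or an acute
#'   change in mental status, **and** no documented alternate (non-urinary)
#'   explanation for those signs. UTI is then a diagnosis of exclusion.
#'
#' Questions are asked in order with short-circuiting, so `fired_question` is
#' the lowest-numbered affirmative question. If none fires, testing and
#' treatment are not indicated. Poor-historian status does not by itself
#' indicate treatment: Q2 evaluates documented localized flags only, and such
#' patients reach the rule through Q3.
#'
#' @param cohort A cohort tibble (see [cohort_columns()]), or a single record
#'   from [uti_record()].
#' @return A tibble with one row per record: `record_id`, `indicated`
#'   (logical), `fired_question` (one of `"Q1_special_population"`,
#'   `"Q2_localized_symptoms"`, `"Q3_systemic_no_alternate"`, `"none"`), and
#'   a human-readable `rationale`.
#' @examples
#' cohort <- dplyr::bind_rows(
#'   uti_record("A", dysuria = TRUE),
#'   uti_record("B", fever = TRUE,
#'              alternate_explanation_for_systemic = "pneumonia")
#' )
#' cdst_evaluate(cohort)
#' @export
cdst_evaluate <- function(cohort) {
  cohort <- validate_cohort(cohort)
  q1 <- Reduce(`|`, cohort[special_flags])
  q2 <- Reduce(`|`, cohort[localized_symptoms])
  systemic <- Reduce(`|`, cohort[systemic_signs])
  q3 <- systemic & is.na(cohort$alternate_explanation_for_systemic)

  fired <- dplyr::case_when(
    q1 ~ "Q1_special_population",
    q2 ~ "Q2_localized_symptoms",
    q3 ~ "Q3_systemic_no_alternate",
    .default = "none"
  )
  name_flags <- function(row, flags) {
    paste(flags[unlist(row[flags])], collapse = ", ")
  }
  rationale <- vapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    switch(
      fired[i],
      Q1_special_population = paste0(
        "special population: ", name_flags(row, special_flags)),
      Q2_localized_symptoms = paste0(
        "localized urinary symptoms: ", name_flags(row, localized_symptoms)),
      Q3_systemic_no_alternate = paste0(
        "systemic signs without alternate explanation: ",
        name_flags(row, systemic_signs)),
      none = if (systemic[i]) {
        paste0("systemic signs explained by: ",
               row$alternate_explanation_for_systemic)
      } else {
        "no qualifying indication, symptoms, or systemic signs"
      }
    )
  }, character(1))

  tibble::tibble(
    record_id = cohort$record_id,
    indicated = fired != "none",
    fired_question = fired,
    rationale = rationale
  )
}
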