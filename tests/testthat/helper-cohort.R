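# Shared toy-cohort builders.

toy_courses <- function(...) {
  d <- c(...)
  tibble::tibble(agent_class = names(d), days_of_therapy = as.integer(d))
}

# a small mixed cohort touching every syndrome stratum
toy_cohort <- function() {
  dplyr::bind_rows(
    uti_record("T1", dysuria = TRUE, truly_needed = TRUE,
               courses = toy_courses(other = 5)),
    uti_record("T2", flank_pain = TRUE, fever = TRUE, truly_needed = TRUE,
               courses = toy_courses(third_generation_cephalosporin = 4)),
    uti_record("T3", fever = TRUE,
               alternate_explanation_for_systemic = "pneumonia",
               documented_non_urinary_source = "pneumonia",
               courses = toy_courses(other = 3)),
    uti_record("T4", pre_endourological_procedure = TRUE, truly_needed = TRUE,
               courses = toy_courses(amoxicillin_clavulanate = 2)),
    uti_record("T5", courses = toy_courses(other = 7))
  )
}

# expand every combination of rule-relevant flags into a cohort; when any
# systemic sign is set, both alternate-explanation states are emitted
truth_table_cohort <- function() {
  flags <- c(special_flags_tt, localized_flags_tt, systemic_flags_tt)
  grid <- do.call(expand.grid, setNames(rep(list(c(FALSE, TRUE)), length(flags)),
                                        flags))
  systemic_any <- grid$fever | grid$clinical_instability |
    grid$acute_mental_status_change
  grid_alt <- grid[systemic_any, , drop = FALSE]
  grid <- rbind(cbind(grid, alt = NA_character_),
                cbind(grid_alt, alt = "other_cause"))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    args <- as.list(grid[i, flags])
    args$record_id <- sprintf("G%04d", i)
    args$alternate_explanation_for_systemic <- grid$alt[i]
    do.call(uti_record, args)
  })
  dplyr::bind_rows(rows)
}

special_flags_tt <- c("pregnant", "pre_endourological_procedure",
                      "renal_transplant_within_60_days")
localized_flags_tt <- c("urgency", "frequency", "dysuria", "suprapubic_pain",
                        "pelvic_discomfort", "flank_pain")
systemic_flags_tt <- c("fever", "clinical_instability",
                       "acute_mental_status_change")

# independent nested-conditional statement of the 3-question rule, written
# as plain if/else over a single record row
oracle_decision <- function(row) {
  if (row$pregnant || row$pre_endourological_procedure ||
      row$renal_transplant_within_60_days) {
    return("Q1_special_population")
  }
  if (row$urgency || row$frequency || row$dysuria || row$suprapubic_pain ||
      row$pelvic_discomfort || row$flank_pain) {
    return("Q2_localized_symptoms")
  }
  if (row$fever || row$clinical_instability || row$acute_mental_status_change) {
    if (is.na(row$alternate_explanation_for_systemic)) {
      return("Q3_systemic_no_alternate")
    }
  }
  "none"
}
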