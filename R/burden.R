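#' Aggregate antibiotic days of therapy by appropriateness and agent class
#'
#' Days of therapy (DOT) are per-agent calendar days summed over agents: a
#' patient on two drugs for three days contributes six days. A course's days
#' count as unjustified when its *record* was treated inappropriately
#' (treatment without documented urinary symptoms or a specific ASB
#' indication) — appropriateness is a patient-level property applied to all
#' of that patient's courses. Outpatient continuation prescriptions, when
#' present in the input, are part of `days_of_therapy`.
#'
#' @param cohort A cohort tibble.
#' @param inappropriate Either a logical vector aligned with `cohort` rows or
#'   the [cdst_adjudicate()] output (matched by `record_id`). Defaults to
#'   adjudicating the cohort.
#' @return A `burden_summary` object: `total_days`, `unjustified_days`,
#'   `by_class` (tibble of per-class `total_days`/`unjustified_days`, which
#'   sum to the global pair) and `n_records`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' cdst_burden(build_fixture())
#' @export
cdst_burden <- function(cohort, inappropriate = NULL) {
  cohort <- validate_cohort(cohort)
  if (is.null(inappropriate)) inappropriate <- cdst_adjudicate(cohort)
  if (is.data.frame(inappropriate)) {
    idx <- match(cohort$record_id, inappropriate$record_id)
    if (anyNA(idx)) abort("inappropriate labels missing for some record_id values")
    inappropriate <- inappropriate$inappropriate[idx]
  }
  if (length(inappropriate) != nrow(cohort) || anyNA(inappropriate)) {
    abort("inappropriate must be a complete logical vector aligned with the cohort")
  }
  courses <- purrr::map2(cohort$courses, inappropriate, function(cr, bad) {
    dplyr::mutate(cr, unjustified = rep(bad, nrow(cr)))
  }) |>
    purrr::list_rbind()
  if (nrow(cohort) == 0 || nrow(courses) == 0) {
    courses <- tibble::tibble(agent_class = character(),
                              days_of_therapy = integer(),
                              unjustified = logical())
  }
  by_class <- courses |>
    dplyr::summarise(
      total_days = sum(.data$days_of_therapy),
      unjustified_days = sum(.data$days_of_therapy[.data$unjustified]),
      .by = "agent_class"
    ) |>
    dplyr::arrange(dplyr::desc(.data$total_days))
  structure(
    list(
      total_days = sum(by_class$total_days),
      unjustified_days = sum(by_class$unjustified_days),
      by_class = by_class,
      n_records = nrow(cohort)
    ),
    class = "burden_summary"
  )
}

#' Potential reduction in antibiotic use
#'
#' The unjustified share of all antibiotic days, unrounded:
#' `unjustified_days / total_days`. Report formatting (one-decimal
#' percentage) is left to the caller; [format_percent()] rounds half-up.
#'
#' @param summary A `burden_summary` object.
#' @return A proportion in \[0, 1\].
#' @examples
#' reduction_fraction(cdst_burden(build_fixture()))
#' @export
reduction_fraction <- function(summary) {
  if (summary$total_days == 0) abort("reduction undefined: total_days is 0")
  summary$unjustified_days / summary$total_days
}

#' @export
print.burden_summary <- function(x, ...) {
  cat("Antibiotic burden over", x$n_records, "record(s):\n")
  cat("  total days of therapy:", x$total_days, "\n")
  if (x$total_days > 0) {
    cat("  unjustified days:     ", x$unjustified_days,
        sprintf("(%s%%)", format_percent(reduction_fraction(x))), "\n")
  }
  print(x$by_class)
  invisible(x)
}

#' @rdname cdst_burden
#' @param x A `burden_summary` object.
#' @param ... Unused.
#' @method tidy burden_summary
#' @export
tidy.burden_summary <- function(x, ...) {
  dplyr::mutate(
    x$by_class,
    unjustified_fraction = ifelse(.data$total_days > 0,
                                  .data$unjustified_days / .data$total_days, NA_real_)
  )
}

#' @rdname cdst_burden
#' @method glance burden_summary
#' @export
glance.burden_summary <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    total_days = x$total_days,
    unjustified_days = x$unjustified_days,
    reduction_fraction = if (x$total_days > 0) reduction_fraction(x) else NA_real_
  )
}
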