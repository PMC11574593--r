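#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a validation result as an annotated confusion matrix
#'
#' @param object A `cdst_validation` object from [cdst_validate()].
#' @param ... Unused.
#' @return A ggplot: a 2x2 tile plot of tool indication versus adjudicated
#'   true need, with cell counts, subtitled with the accuracy estimates.
#' @method autoplot cdst_validation
#' @export
autoplot.cdst_validation <- function(object, ...) {
  cm <- object$confusion
  acc <- object$accuracy
  cells <- tibble::tibble(
    tool = factor(rep(c("indicated", "not indicated"), each = 2),
                  levels = c("indicated", "not indicated")),
    truth = factor(rep(c("needed", "not needed"), 2),
                   levels = c("not needed", "needed")),
    n = c(cm$tp, cm$fp, cm$fn, cm$tn)
  )
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$truth, y = .data$tool,
                                      fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 6) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::labs(
      x = "Adjudicated: treatment truly needed",
      y = "Tool recommendation",
      title = "3-question rule vs full-stay adjudication",
      subtitle = sprintf("sensitivity %s%%, specificity %s%% (n = %d)",
                         format_percent(acc$sensitivity),
                         format_percent(acc$specificity), object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an antibiotic burden summary
#'
#' @param object A `burden_summary` object from [cdst_burden()].
#' @param ... Unused.
#' @return A ggplot: stacked bars of days of therapy per agent class, split
#'   into justified and unjustified days.
#' @method autoplot burden_summary
#' @export
autoplot.burden_summary <- function(object, ...) {
  long <- object$by_class |>
    dplyr::mutate(justified_days = .data$total_days - .data$unjustified_days) |>
    tidyr::pivot_longer(c("justified_days", "unjustified_days"),
                        names_to = "appropriateness", values_to = "days") |>
    dplyr::mutate(appropriateness = ifelse(
      .data$appropriateness == "justified_days", "justified", "unjustified"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$agent_class, -.data$days),
    y = .data$days, fill = .data$appropriateness)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(justified = "grey65",
                                          unjustified = "firebrick")) +
    ggplot2::labs(x = NULL, y = "Days of therapy",
                  title = "Antibiotic days by class and appropriateness",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Plot syndrome composition of an adjudicated cohort
#'
#' @param labels Output of [cdst_adjudicate()].
#' @return A ggplot bar chart of syndrome counts, ASB split by whether a
#'   guideline treatment indication was present.
#' @export
plot_syndromes <- function(labels) {
  dat <- labels |>
    dplyr::mutate(stratum = dplyr::case_when(
      .data$syndrome == "asb" & .data$asb_with_treatment_indication ~
        "asb (treatment indicated)",
      .data$syndrome == "asb" ~ "asb (no indication)",
      .default = .data$syndrome
    )) |>
    dplyr::count(.data$stratum)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$stratum, -.data$n), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "Cases", title = "Adjudicated syndromes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
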