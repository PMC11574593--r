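#' Cross-tabulate tool indication against the adjudicated true need
#'
#' @param decisions Output of [cdst_evaluate()] (or any tibble with
#'   `record_id` and logical `indicated`).
#' @param truths Output of [cdst_true_need()] (or any tibble with
#'   `record_id` and logical `truly_needed`).
#' @return A `cdst_confusion` object with integer cells `tp` (indicated and
#'   needed), `fp` (indicated, not needed), `fn` (not indicated, needed) and
#'   `tn` (neither); cells sum to the number of records.
#' @examples
#' cohort <- build_fixture()
#' cdst_confusion(cdst_evaluate(cohort), cdst_true_need(cohort))
#' @export
cdst_confusion <- function(decisions, truths) {
  if (nrow(decisions) != nrow(truths)) {
    abort("decisions and truths must cover the same records (length mismatch)")
  }
  if (!setequal(decisions$record_id, truths$record_id) ||
      anyDuplicated(decisions$record_id) || anyDuplicated(truths$record_id)) {
    abort("decisions and truths must cover the same unique record_id set")
  }
  truths <- truths[match(decisions$record_id, truths$record_id), ]
  ind <- decisions$indicated
  need <- truths$truly_needed
  structure(
    list(
      tp = sum(ind & need), fp = sum(ind & !need),
      fn = sum(!ind & need), tn = sum(!ind & !need)
    ),
    class = "cdst_confusion"
  )
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts of tool indication
#'   versus adjudicated true need.
#' @return A `cdst_confusion` object.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("Confusion cells must be non-negative integers")
  }
  structure(as.list(as.integer(cells)) |> setNames(names(cells)),
            class = "cdst_confusion")
}

#' @export
print.cdst_confusion <- function(x, ...) {
  cat("Tool indication vs adjudicated true need (n =",
      x$tp + x$fp + x$fn + x$tn, ")\n")
  m <- as.matrix(x)
  print(m)
  invisible(x)
}

#' @export
as.matrix.cdst_confusion <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
         dimnames = list(tool = c("indicated", "not_indicated"),
                         truth = c("needed", "not_needed")))
}

#' Exact Clopper-Pearson confidence interval for a binomial proportion
#'
#' Computed from beta-distribution quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), upper =
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param x Number of successes.
#' @param n Number of trials (positive).
#' @param level Confidence level, default 0.95.
#' @return A length-2 numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (n <= 0 || x < 0 || x > n) abort("Need 0 <= x <= n with n > 0")
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower, upper)
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP). Intervals are
#' exact Clopper-Pearson by default — chosen because a specificity estimated
#' at 100% degenerates under Wald intervals.
#'
#' @param cm A `cdst_confusion` object.
#' @param ci_level Confidence level for the intervals, default 0.95.
#' @param ci_method Interval method; only `"clopper-pearson"` is provided.
#' @return A `cdst_accuracy` object: proportions `sensitivity` and
#'   `specificity` with `sensitivity_ci` / `specificity_ci` (each
#'   `c(lower, upper)`).
#' @examples
#' cdst_accuracy(confusion_matrix(73, 0, 1, 50))
#' @export
cdst_accuracy <- function(cm, ci_level = 0.95, ci_method = "clopper-pearson") {
  ci_method <- match.arg(ci_method)
  if (cm$tp + cm$fn == 0) abort("Sensitivity undefined: no truly-needed records (tp + fn = 0)")
  if (cm$tn + cm$fp == 0) abort("Specificity undefined: no not-needed records (tn + fp = 0)")
  structure(
    list(
      sensitivity = cm$tp / (cm$tp + cm$fn),
      specificity = cm$tn / (cm$tn + cm$fp),
      sensitivity_ci = clopper_pearson(cm$tp, cm$tp + cm$fn, ci_level),
      specificity_ci = clopper_pearson(cm$tn, cm$tn + cm$fp, ci_level),
      ci_level = ci_level,
      confusion = cm
    ),
    class = "cdst_accuracy"
  )
}

#' @export
print.cdst_accuracy <- function(x, ...) {
  lv <- 100 * x$ci_level
  cat(sprintf("Sensitivity: %s%% (%g%% CI %s-%s)\n",
              format_percent(x$sensitivity), lv,
              format_percent(x$sensitivity_ci[1]),
              format_percent(x$sensitivity_ci[2])))
  cat(sprintf("Specificity: %s%% (%g%% CI %s-%s)\n",
              format_percent(x$specificity), lv,
              format_percent(x$specificity_ci[1]),
              format_percent(x$specificity_ci[2])))
  invisible(x)
}

#' Validate the rule against the reference standard on a cohort
#'
#' Convenience pipeline: runs [cdst_evaluate()] and [cdst_true_need()],
#' cross-tabulates them with [cdst_confusion()], and estimates accuracy with
#' [cdst_accuracy()].
#'
#' @param cohort A cohort tibble with adjudication fields.
#' @param ci_level Confidence level for the exact intervals.
#' @return A `cdst_validation` object with components `confusion`,
#'   `accuracy` and `n`; supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @examples
#' glance(cdst_validate(build_fixture()))
#' @export
cdst_validate <- function(cohort, ci_level = 0.95) {
  cohort <- validate_cohort(cohort)
  cm <- cdst_confusion(cdst_evaluate(cohort), cdst_true_need(cohort))
  structure(
    list(confusion = cm, accuracy = cdst_accuracy(cm, ci_level), n = nrow(cohort)),
    class = "cdst_validation"
  )
}

#' @export
print.cdst_validation <- function(x, ...) {
  print(x$confusion)
  cat("\n")
  print(x$accuracy)
  invisible(x)
}

#' @rdname cdst_validate
#' @param x A `cdst_validation` object.
#' @param ... Unused.
#' @method tidy cdst_validation
#' @export
tidy.cdst_validation <- function(x, ...) {
  acc <- x$accuracy
  tibble::tibble(
    metric = c("sensitivity", "specificity"),
    estimate = c(acc$sensitivity, acc$specificity),
    conf.low = c(acc$sensitivity_ci[1], acc$specificity_ci[1]),
    conf.high = c(acc$sensitivity_ci[2], acc$specificity_ci[2])
  )
}

#' @rdname cdst_validate
#' @method glance cdst_validation
#' @export
glance.cdst_validation <- function(x, ...) {
  cm <- x$confusion
  acc <- x$accuracy
  tibble::tibble(
    n = x$n, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
    sensitivity = acc$sensitivity, specificity = acc$specificity
  )
}

#' Compare a binary marker between two groups
#'
#' Pearson chi-square test on the 2x2 table of marker presence by group.
#' Records with the marker missing are excluded before testing (missing data
#' are excluded from the specific analyses affected). No continuity
#' correction by default; set `correct = TRUE` for the Yates-corrected
#' variant. Degenerate tables in which the marker (or group) margin is empty
#' have no association to test and return statistic 0, p = 1.
#'
#' @param group_a,group_b Logical vectors of marker presence (NA = marker
#'   not measured).
#' @param marker Label for the marker, carried into the output.
#' @param correct Apply the Yates continuity correction? Default `FALSE`.
#' @return A one-row tibble: `marker`, `group_a_fraction`,
#'   `group_b_fraction`, `n_a`, `n_b`, `statistic`, `p_value`, `method`.
#' @examples
#' compare_proportions(rep(c(TRUE, FALSE), c(8, 2)),
#'                     rep(c(TRUE, FALSE), c(2, 8)))
#' @export
compare_proportions <- function(group_a, group_b, marker = "marker",
                                correct = FALSE) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) == 0 || length(b) == 0) {
    abort("A group is empty after excluding missing marker values")
  }
  tab <- rbind(a = c(sum(a), sum(!a)), b = c(sum(b), sum(!b)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stat <- 0
    p <- 1
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  tibble::tibble(
    marker = marker,
    group_a_fraction = mean(a), group_b_fraction = mean(b),
    n_a = length(a), n_b = length(b),
    statistic = stat, p_value = p,
    method = paste0("Pearson chi-square",
                    if (correct) " with Yates correction" else "")
  )
}

#' Compare a continuous marker between two groups
#'
#' Two-sample t-test; Welch (unequal variances) by default, the safer choice
#' when variances are unknown. Missing values are excluded per group.
#'
#' @param group_a,group_b Numeric vectors (each needs at least 2 non-missing
#'   values).
#' @param marker Label for the marker.
#' @param var_equal Assume equal variances (Student's t)? Default `FALSE`
#'   (Welch).
#' @return A one-row tibble: `marker`, `group_a_mean`, `group_b_mean`,
#'   `n_a`, `n_b`, `statistic`, `p_value`, `method`.
#' @examples
#' compare_means(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_means <- function(group_a, group_b, marker = "marker",
                          var_equal = FALSE) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 non-missing values")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    stat <- 0
    p <- 1
  } else {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  tibble::tibble(
    marker = marker,
    group_a_mean = mean(a), group_b_mean = mean(b),
    n_a = length(a), n_b = length(b),
    statistic = stat, p_value = p,
    method = if (var_equal) "Student t-test" else "Welch t-test"
  )
}

#' Urinalysis marker comparisons between UTI and ASB cases
#'
#' Compares leukocyturia, visible bacteria and nitrite positivity
#' (chi-square on proportions) and the leukocyte count (Welch t-test on
#' means, cells/uL) between adjudicated UTI cases (pyelonephritis or
#' cystitis) and ASB cases, among records with an available urinalysis.
#'
#' @param cohort A cohort tibble.
#' @param labels Optional precomputed [cdst_adjudicate()] output.
#' @return A tibble with one row per marker; for proportions `group_a_*`
#'   refers to the UTI group and `group_b_*` to the ASB group.
#' @export
compare_urinalysis <- function(cohort, labels = cdst_adjudicate(cohort)) {
  cohort <- validate_cohort(cohort)
  grp <- labels$syndrome[match(cohort$record_id, labels$record_id)]
  uti <- cohort[grp %in% c("pyelonephritis", "cystitis") & cohort$ua_available, ]
  asb <- cohort[grp == "asb" & cohort$ua_available, ]
  props <- purrr::map(urinalysis_markers, function(m) {
    compare_proportions(uti[[m]], asb[[m]], marker = m)
  })
  means <- compare_means(uti$leukocyte_count, asb$leukocyte_count,
                         marker = "leukocyte_count")
  dplyr::bind_rows(c(props, list(means)))
}

#' Half-up rounding
#'
#' Rounds halves away from zero (so 98.65 -> 98.7 at one decimal), unlike
#' [round()]'s round-half-even. Used for all reported percentages.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a proportion as a one-decimal percentage string
#'
#' @param p Proportion in \[0, 1\].
#' @param digits Decimal places (default 1).
#' @return Character vector like `"98.6"`.
#' @export
format_percent <- function(p, digits = 1) {
  formatC(round_half_up(100 * p, digits), format = "f", digits = digits)
}
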