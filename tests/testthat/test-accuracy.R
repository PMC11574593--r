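test_that("confusion counting matches hand enumeration over all label assignments", {
  # brute force: 3 records, every combination of indicated x truly_needed
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), 6))
  for (i in seq_len(nrow(grid))) {
    ind <- unlist(grid[i, 1:3])
    need <- unlist(grid[i, 4:6])
    cm <- cdst_confusion(
      tibble::tibble(record_id = c("a", "b", "c"), indicated = ind),
      tibble::tibble(record_id = c("a", "b", "c"), truly_needed = need)
    )
    expect_identical(cm$tp, sum(ind & need))
    expect_identical(cm$fp, sum(ind & !need))
    expect_identical(cm$fn, sum(!ind & need))
    expect_identical(cm$tn, sum(!ind & !need))
    expect_identical(cm$tp + cm$fp + cm$fn + cm$tn, 3L)
  }
})

test_that("confusion matches records by id and rejects mismatched sets", {
  dec <- tibble::tibble(record_id = c("a", "b"), indicated = c(TRUE, FALSE))
  tru <- tibble::tibble(record_id = c("b", "a"), truly_needed = c(TRUE, TRUE))
  cm <- cdst_confusion(dec, tru)  # order differs; must align by id
  expect_identical(c(cm$tp, cm$fn), c(1L, 1L))
  expect_error(cdst_confusion(dec, tru[1, ]), "length mismatch")
  tru$record_id <- c("b", "z")
  expect_error(cdst_confusion(dec, tru), "record_id set")
})

test_that("sensitivity and specificity follow the defining ratios", {
  acc <- cdst_accuracy(confusion_matrix(73, 0, 1, 50))
  expect_equal(acc$sensitivity, 73 / 74)
  expect_equal(acc$specificity, 1)
  expect_identical(format_percent(acc$sensitivity), "98.6")
  # a perfect classifier scores (1, 1) for any margin sizes
  for (k in c(1, 5)) for (m in c(1, 9)) {
    acc <- cdst_accuracy(confusion_matrix(k, 0, 0, m))
    expect_equal(c(acc$sensitivity, acc$specificity), c(1, 1))
  }
  expect_error(cdst_accuracy(confusion_matrix(0, 3, 0, 1)), "Sensitivity undefined")
  expect_error(cdst_accuracy(confusion_matrix(3, 0, 1, 0)), "Specificity undefined")
})

test_that("Clopper-Pearson intervals agree with the exact binomial-test oracle", {
  cases <- list(c(1, 2), c(73, 74), c(50, 50), c(0, 20), c(17, 40))
  for (cs in cases) {
    ours <- clopper_pearson(cs[1], cs[2], 0.95)
    oracle <- stats::binom.test(cs[1], cs[2])$conf.int
    expect_equal(ours, as.numeric(oracle), tolerance = 1e-10,
                 label = paste(cs, collapse = "/"))
  }
  # point estimates always fall inside their intervals
  acc <- cdst_accuracy(confusion_matrix(1, 1, 1, 1))
  expect_equal(acc$sensitivity, 0.5)
  expect_true(acc$sensitivity_ci[1] <= 0.5 && 0.5 <= acc$sensitivity_ci[2])
  expect_true(all(c(acc$sensitivity_ci, acc$specificity_ci) >= 0) &&
                all(c(acc$sensitivity_ci, acc$specificity_ci) <= 1))
})

test_that("chi-square comparison matches the closed-form 2x2 statistic", {
  # 8/10 vs 2/10: all expected cells are 5, X2 = 4 * (3^2 / 5) = 7.2
  res <- compare_proportions(rep(c(TRUE, FALSE), c(8, 2)),
                             rep(c(TRUE, FALSE), c(2, 8)))
  expect_equal(res$statistic, 7.2)
  expect_equal(res$p_value, stats::pchisq(7.2, df = 1, lower.tail = FALSE))
  expect_equal(res$group_a_fraction, 0.8)
  # identical or degenerate proportions carry no association
  same <- compare_proportions(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 5))
  expect_equal(c(same$statistic, same$p_value), c(0, 1))
  allt <- compare_proportions(rep(TRUE, 6), rep(TRUE, 4))
  expect_equal(c(allt$statistic, allt$p_value), c(0, 1))
  # missing markers are excluded; a group empty after exclusion errors
  res <- compare_proportions(c(TRUE, NA, FALSE, TRUE), c(NA, FALSE, TRUE, NA))
  expect_identical(c(res$n_a, res$n_b), c(3L, 2L))
  expect_error(compare_proportions(c(NA, NA), c(TRUE, FALSE)), "empty")
})

test_that("Welch comparison matches hand arithmetic and is symmetric in group labels", {
  # {1,2,3} vs {4,5,6}: t = -3 / sqrt(1/3 + 1/3), df = 4
  res <- compare_means(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3 / sqrt(2 / 3))
  expect_equal(res$p_value, 2 * stats::pt(-3 / sqrt(2 / 3), df = 4))
  expect_equal(c(res$group_a_mean, res$group_b_mean), c(2, 5))
  # identical groups
  same <- compare_means(c(2, 4, 6), c(2, 4, 6))
  expect_equal(c(same$statistic, same$p_value), c(0, 1))
  # swapping groups mirrors the statistic and keeps p
  swapped <- compare_means(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)
  swp <- compare_proportions(rep(c(TRUE, FALSE), c(2, 8)),
                             rep(c(TRUE, FALSE), c(8, 2)))
  expect_equal(swp$p_value,
               compare_proportions(rep(c(TRUE, FALSE), c(8, 2)),
                                   rep(c(TRUE, FALSE), c(2, 8)))$p_value)
  expect_error(compare_means(c(1), c(2, 3)), "at least 2")
})

test_that("larger shifts and larger samples strengthen the evidence monotonically", {
  a <- c(10, 12, 14, 16, 18)
  stats_by_shift <- vapply(
    0:4, function(s) abs(compare_means(a, a + s)$statistic), numeric(1))
  expect_true(all(diff(stats_by_shift) > 0))
  # same proportion difference observed at growing n drives p down
  p_by_n <- vapply(c(10, 20, 40, 80), function(n) {
    compare_proportions(rep(c(TRUE, FALSE), c(0.8 * n, 0.2 * n)),
                        rep(c(TRUE, FALSE), c(0.2 * n, 0.8 * n)))$p_value
  }, numeric(1))
  expect_true(all(diff(p_by_n) < 0))
})

test_that("urinalysis comparison excludes unavailable samples and covers all four markers", {
  cohort <- build_fixture()
  res <- compare_urinalysis(cohort)
  expect_identical(res$marker, c("leukocyturia", "bacteria_seen",
                                 "nitrites_positive", "leukocyte_count"))
  # denominators: urinalysis available for 58 UTI and 27 ASB records
  expect_true(all(res$n_a == 58))
  expect_true(all(res$n_b == 27))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("half-up rounding reports percentages the way the accuracy summary prints them", {
  expect_equal(round_half_up(98.65, 1), 98.7)  # round() would give 98.6
  expect_equal(round_half_up(c(0.05, -0.05), 1), c(0.1, -0.1))
  expect_identical(format_percent(73 / 74), "98.6")
  expect_identical(format_percent(265 / 787), "33.7")
})
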