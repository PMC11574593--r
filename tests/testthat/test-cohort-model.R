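test_that("serialization round-trips losslessly in both dialects", {
  cohort <- dplyr::bind_rows(
    uti_record("A1", age_years = 44.5, dysuria = TRUE, poor_historian = TRUE,
               ua_available = TRUE, leukocyturia = TRUE, leukocyte_count = 120,
               truly_needed = TRUE,
               courses = toy_courses(third_generation_cephalosporin = 3, other = 2)),
    uti_record("A2", fever = TRUE,
               alternate_explanation_for_systemic = "pneumonia",
               documented_non_urinary_source = "pneumonia",
               notes = "free text, with commas"),
    uti_record("A3")  # all optionals absent, no courses
  )
  for (fmt in c("tabular", "structured")) {
    path <- withr::local_tempfile(fileext = if (fmt == "tabular") ".csv" else ".json")
    write_cohort(cohort, path, fmt)
    back <- suppressMessages(read_cohort(path, fmt))
    expect_equal(as.data.frame(back), as.data.frame(cohort), ignore_attr = TRUE)
  }
})

test_that("absent optional fields serialize as the empty missing token, not zero", {
  rec <- uti_record("A1")  # urinalysis unavailable
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(rec, path)
  lines <- readLines(path)
  row <- strsplit(lines[2], ",")[[1]]
  header <- strsplit(lines[1], ",")[[1]]
  expect_identical(row[match("leukocyturia", header)], "")
  expect_identical(row[match("leukocyte_count", header)], "")
  expect_identical(row[match("dysuria", header)], "false")
})

test_that("a header-only file reads as an empty cohort that still writes back", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(uti_record()[0, ], path)
  cohort <- read_cohort(path)
  expect_identical(nrow(cohort), 0L)
  expect_named(cohort, cohort_columns())
})

test_that("missing mandatory fields raise naming the record; missing flags are coded false with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(uti_record("B1", dysuria = TRUE), path)
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  tab$sex <- ""
  readr::write_csv(tab, path, na = "")
  expect_error(read_cohort(path), "mandatory field 'sex'.*B1")

  tab$sex <- "female"
  tab$fever <- ""
  readr::write_csv(tab, path, na = "")
  expect_warning(cohort <- read_cohort(path), "Missing fever coded as false")
  expect_false(cohort$fever)
})

test_that("duplicate record ids and malformed values are rejected or flagged", {
  cohort <- dplyr::bind_rows(uti_record("D1"), uti_record("D2"))
  cohort$record_id <- c("D1", "D1")
  expect_error(validate_cohort(cohort), "Duplicate record_id: D1")

  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(uti_record("B1", ua_available = TRUE, leukocyte_count = 10), path)
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  tab$leukocyte_count <- "not-a-number"
  readr::write_csv(tab, path, na = "")
  expect_warning(cohort <- read_cohort(path), "Unparseable leukocyte_count")
  expect_true(is.na(cohort$leukocyte_count))
})

test_that("repeated prescriptions of the same agent class are summed on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(uti_record("C1", courses = toy_courses(other = 2)), path)
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  tab$agent_class_2 <- "other"
  tab$dot_2 <- "3"
  readr::write_csv(tab, path, na = "")
  cohort <- read_cohort(path)
  expect_equal(cohort$courses[[1]]$days_of_therapy, 5L)
  expect_equal(cohort$courses[[1]]$agent_class, "other")
})

test_that("eligibility filtering drops minors, ED discharges and order artifacts", {
  cohort <- dplyr::bind_rows(
    uti_record("E1", age_years = 17),
    uti_record("E2"), uti_record("E3"), uti_record("E4"), uti_record("E5")
  )
  meta <- tibble::tibble(
    record_id = paste0("E", 1:5),
    admitted = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    observation_only = c(FALSE, FALSE, FALSE, FALSE, FALSE),
    onetime_order = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  out <- suppressMessages(apply_eligibility(cohort, meta))
  expect_identical(out$record_id, c("E4", "E5"))
  expect_equal(
    attr(out, "exclusions"),
    c(under_18 = 1L, ed_discharge = 1L, observation_only = 0L, onetime_order = 1L)
  )
  # idempotence
  again <- suppressMessages(apply_eligibility(out, meta[4:5, ]))
  expect_equal(as.data.frame(again), as.data.frame(out), ignore_attr = TRUE)
  # no-exclusion cohort passes through unchanged
  clean <- toy_cohort()
  expect_equal(as.data.frame(apply_eligibility(clean)), as.data.frame(clean),
               ignore_attr = TRUE)
})

test_that("underage records survive reading but not eligibility", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(uti_record("M1", age_years = 17), path)
  cohort <- read_cohort(path)
  expect_identical(nrow(cohort), 1L)
  expect_identical(nrow(suppressMessages(apply_eligibility(cohort))), 0L)
})

test_that("cohort invariants are enforced", {
  rec <- uti_record("V1")
  bad <- rec
  bad$alternate_explanation_for_systemic <- "pneumonia"  # no systemic sign
  expect_error(validate_cohort(bad), "alternate_explanation_for_systemic")
  bad <- rec
  bad$leukocyturia <- TRUE  # urinalysis unavailable
  expect_error(validate_cohort(bad), "ua_available")
  bad <- rec
  bad$courses <- list(tibble::tibble(agent_class = "other", days_of_therapy = 0L))
  expect_error(validate_cohort(bad), "courses")
})
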