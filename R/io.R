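# Serialization of cohorts.
#
# Tabular dialect: comma-separated UTF-8 with one header row. Booleans are
# written as literal "true"/"false" (case-insensitive on read); an empty cell
# is the missing token, distinct from explicit false — the study distinguishes
# "no symptom documented" from "patient unable to report". Antibiotic courses
# are flattened as column groups agent_class_1/dot_1 .. agent_class_3/dot_3
# with an other_dot spillover (days of any fourth or later class, re-read as
# class "other").
#
# Structured dialect: a JSON array with one object per patient; absent
# optional fields are omitted from the object.

mandatory_fields <- c("record_id", "age_years", "sex")

optional_bool_na <- urinalysis_markers  # may legitimately stay missing
bool_fields <- c(special_flags, localized_symptoms, systemic_signs,
                 "poor_historian", "ua_available")

course_cols <- function() {
  c(paste0(rep(c("agent_class_", "dot_"), 3), rep(1:3, each = 2)), "other_dot")
}

csv_columns <- function() {
  cols <- cohort_columns()
  i <- match("courses", cols)
  c(cols[seq_len(i - 1)], course_cols(), cols[-seq_len(i)])
}

#' Write a cohort to disk
#'
#' @param cohort A validated cohort tibble.
#' @param path Output file path.
#' @param format `"tabular"` (CSV, course list flattened to
#'   `agent_class_k`/`dot_k` column groups) or `"structured"` (JSON, fully
#'   lossless).
#' @return `path`, invisibly.
#' @seealso [read_cohort()] for the inverse; the round trip reproduces every
#'   field, including absent optionals.
#' @export
write_cohort <- function(cohort, path, format = c("tabular", "structured")) {
  format <- match.arg(format)
  cohort <- validate_cohort(cohort)
  if (format == "tabular") {
    write_cohort_csv(cohort, path)
  } else {
    write_cohort_json(cohort, path)
  }
  invisible(path)
}

flatten_courses <- function(courses) {
  out <- as.list(setNames(
    rep(list(rep(NA_character_, length(courses))), 3),
    paste0("agent_class_", 1:3)
  ))
  for (k in 1:3) out[[paste0("dot_", k)]] <- rep(NA_integer_, length(courses))
  out$other_dot <- rep(NA_integer_, length(courses))
  for (i in seq_along(courses)) {
    cr <- courses[[i]]
    if (nrow(cr) == 0) next
    k_max <- min(nrow(cr), 3)
    for (k in seq_len(k_max)) {
      out[[paste0("agent_class_", k)]][i] <- cr$agent_class[k]
      out[[paste0("dot_", k)]][i] <- as.integer(cr$days_of_therapy[k])
    }
    if (nrow(cr) > 3) {
      out$other_dot[i] <- as.integer(sum(cr$days_of_therapy[-(1:3)]))
    }
  }
  tibble::as_tibble(out[c(rbind(paste0("agent_class_", 1:3), paste0("dot_", 1:3)),
                          "other_dot")])
}

fmt_bool <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))

write_cohort_csv <- function(cohort, path) {
  flat <- dplyr::select(cohort, -"courses")
  for (f in c(bool_fields, optional_bool_na, "truly_needed")) {
    flat[[f]] <- fmt_bool(flat[[f]])
  }
  flat <- dplyr::bind_cols(flat, flatten_courses(cohort$courses))
  flat <- flat[, csv_columns()]
  readr::write_csv(flat, path, na = "")
}

write_cohort_json <- function(cohort, path) {
  recs <- lapply(seq_len(nrow(cohort)), function(i) {
    row <- as.list(cohort[i, setdiff(cohort_columns(), "courses")])
    row <- row[!vapply(row, function(v) is.na(v[1]), logical(1))]
    cr <- cohort$courses[[i]]
    row$courses <- lapply(seq_len(nrow(cr)), function(k) {
      list(agent_class = cr$agent_class[k],
           days_of_therapy = as.integer(cr$days_of_therapy[k]))
    })
    row
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a cohort from disk
#'
#' Reads the tabular (CSV) or structured (JSON) cohort dialect back into a
#' validated cohort tibble. Missing mandatory fields (`record_id`,
#' `age_years`, `sex`) raise an error naming the record and field. Missing
#' special-population and symptom flags are coded `FALSE` with a warning
#' (absence of information is not permitted for these); urinalysis fields and
#' notes stay absent (`NA`). Multiple courses of the same agent class are
#' summed on read, matching class-level day reporting. When a record has all
#' localized flags `FALSE` but is marked a poor historian, a message notes
#' that localized symptoms are "not documentable" rather than absent.
#'
#' @param path File to read.
#' @param format `"tabular"` or `"structured"`.
#' @return A cohort tibble, one row per record, in file order.
#' @export
read_cohort <- function(path, format = c("tabular", "structured")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  cohort <- if (format == "tabular") read_cohort_csv(path) else read_cohort_json(path)
  ph_undoc <- cohort$poor_historian &
    !Reduce(`|`, cohort[localized_symptoms])
  if (any(ph_undoc)) {
    inform(paste0(
      sum(ph_undoc), " poor-historian record(s) have no localized flags set; ",
      "localized symptoms are not documentable rather than absent: ",
      paste(utils::head(cohort$record_id[ph_undoc], 5), collapse = ", ")
    ))
  }
  validate_cohort(cohort)
}

parse_bool <- function(x, field, ids, mandatory_false = FALSE) {
  x_low <- tolower(trimws(ifelse(is.na(x), "", x)))
  out <- rep(NA, length(x))
  out[x_low == "true"] <- TRUE
  out[x_low == "false"] <- FALSE
  bad <- !(x_low %in% c("", "true", "false"))
  if (any(bad)) {
    warn(paste0("Unparseable ", field, " treated as missing in record(s): ",
                paste(utils::head(ids[bad], 5), collapse = ", ")))
  }
  if (mandatory_false && anyNA(out)) {
    warn(paste0("Missing ", field, " coded as false in record(s): ",
                paste(utils::head(ids[is.na(out)], 5), collapse = ", ")))
    out[is.na(out)] <- FALSE
  }
  out
}

collect_courses <- function(flat) {
  lapply(seq_len(nrow(flat)), function(i) {
    cls <- character()
    dot <- integer()
    for (k in 1:3) {
      cl <- flat[[paste0("agent_class_", k)]][i]
      d <- flat[[paste0("dot_", k)]][i]
      if (!is.na(cl) && !is.na(d)) {
        cls <- c(cls, cl)
        dot <- c(dot, as.integer(d))
      }
    }
    if (!is.na(flat$other_dot[i])) {
      cls <- c(cls, "other")
      dot <- c(dot, as.integer(flat$other_dot[i]))
    }
    if (length(cls) == 0) return(empty_courses())
    # same agent class listed more than once: sum its days
    tibble::tibble(agent_class = cls, days_of_therapy = dot) |>
      dplyr::summarise(days_of_therapy = sum(.data$days_of_therapy),
                       .by = "agent_class")
  })
}

read_cohort_csv <- function(path) {
  flat <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          na = character(), progress = FALSE)
  probs <- readr::problems(flat)
  if (nrow(probs) > 0) {
    abort(paste0("Malformed tabular cohort at line ", probs$row[1], ": ",
                 probs$expected[1]))
  }
  missing_cols <- setdiff(csv_columns(), names(flat))
  if (length(missing_cols) > 0) {
    abort(paste0("Tabular cohort missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  flat[flat == ""] <- NA
  if (nrow(flat) == 0) {
    return(uti_record()[0, ])
  }
  ids <- flat$record_id
  for (f in mandatory_fields) {
    if (anyNA(flat[[f]])) {
      bad_row <- which(is.na(flat[[f]]))[1]
      abort(paste0("Missing mandatory field '", f, "' in record ",
                   ifelse(f == "record_id", paste0("at row ", bad_row),
                          ids[bad_row])))
    }
  }
  out <- tibble::tibble(
    record_id = ids,
    age_years = readr::parse_double(flat$age_years),
    sex = tolower(flat$sex)
  )
  if (anyNA(out$age_years)) {
    abort(paste0("Unparseable age_years in record ",
                 ids[which(is.na(out$age_years))[1]]))
  }
  for (f in bool_fields) out[[f]] <- parse_bool(flat[[f]], f, ids, mandatory_false = TRUE)
  out$alternate_explanation_for_systemic <- flat$alternate_explanation_for_systemic
  for (f in optional_bool_na) out[[f]] <- parse_bool(flat[[f]], f, ids)
  out$leukocyte_count <- suppressWarnings(readr::parse_double(
    ifelse(is.na(flat$leukocyte_count), NA_character_, flat$leukocyte_count)))
  unparse <- !is.na(flat$leukocyte_count) & is.na(out$leukocyte_count)
  if (any(unparse)) {
    warn(paste0("Unparseable leukocyte_count treated as missing in record(s): ",
                paste(utils::head(ids[unparse], 5), collapse = ", ")))
  }
  out$courses <- collect_courses(flat)
  out$documented_non_urinary_source <-
    ifelse(is.na(flat$documented_non_urinary_source), "none",
           flat$documented_non_urinary_source)
  out$truly_needed <- parse_bool(flat$truly_needed, "truly_needed", ids)
  out$notes <- flat$notes
  # relocate to canonical order
  out[, cohort_columns()]
}

read_cohort_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(recs) == 0) return(uti_record()[0, ])
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    for (f in mandatory_fields) {
      if (is.null(r[[f]])) {
        abort(paste0("Missing mandatory field '", f, "' in record ",
                     r$record_id %||% paste0("at index ", i)))
      }
    }
    cr <- if (length(r$courses %||% list()) == 0) {
      empty_courses()
    } else {
      tibble::tibble(
        agent_class = vapply(r$courses, function(x) x$agent_class, character(1)),
        days_of_therapy = vapply(r$courses, function(x) as.integer(x$days_of_therapy),
                                 integer(1))
      ) |>
        dplyr::summarise(days_of_therapy = sum(.data$days_of_therapy),
                         .by = "agent_class")
    }
    rec <- uti_record(record_id = r$record_id, age_years = r$age_years,
                      sex = r$sex, courses = cr)
    for (f in c(bool_fields, "truly_needed")) {
      if (!is.null(r[[f]])) rec[[f]] <- isTRUE(r[[f]])
    }
    for (f in optional_bool_na) if (!is.null(r[[f]])) rec[[f]] <- isTRUE(r[[f]])
    if (!is.null(r$leukocyte_count)) rec$leukocyte_count <- as.numeric(r$leukocyte_count)
    if (!is.null(r$alternate_explanation_for_systemic)) {
      rec$alternate_explanation_for_systemic <- r$alternate_explanation_for_systemic
    }
    if (!is.null(r$documented_non_urinary_source)) {
      rec$documented_non_urinary_source <- r$documented_non_urinary_source
    }
    if (!is.null(r$notes)) rec$notes <- r$notes
    rec
  })
  dplyr::bind_rows(rows)
}
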