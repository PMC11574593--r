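#' Configuration for the synthetic cohort generator
#'
#' Default parameters reproduce the validation study's structure: cohort
#' size 124; syndrome mix 50/15/13/46 (pyelonephritis / cystitis / other
#' infection / ASB); 8 of 46 ASB records with a pre-procedural treatment
#' indication; 36 of 124 poor historians; 9 of 46 ASB records with altered
#' mental status explained by another cause; urinalysis available for 85 of
#' 124 records; marker positivity and leukocyte-count distributions chosen
#' to echo the published group summaries (log-normal counts, heavy right
#' skew); antibiotic class mix and per-class day counts calibrated so the
#' expected cohort total is near 787 days; 1 in 13 other-infection records
#' carries a concurrent true UTI (the pneumonia-with-bacteremia pattern).
#'
#' @param n Cohort size.
#' @param syndrome_probabilities Named proportions over
#'   `pyelonephritis`, `cystitis`, `other_infection`, `asb`; must sum to 1.
#' @param asb_procedural_indication_fraction Fraction of ASB records with a
#'   pre-endourological treatment indication.
#' @param poor_historian_fraction Fraction of all records unable to report
#'   symptoms reliably.
#' @param asb_altered_mental_status_fraction Fraction of
#'   non-procedural ASB records with altered mental status attributed to a
#'   documented non-urinary cause.
#' @param urinalysis_availability Probability a record has urinalysis
#'   results.
#' @param marker_probabilities List with elements `uti` and `asb`, each a
#'   named vector of positivity probabilities for `leukocyturia`,
#'   `bacteria_seen`, `nitrites_positive`.
#' @param leukocyte_count_distribution List with elements `uti` and `asb`,
#'   each `c(meanlog, sdlog)` of a log-normal in cells/uL.
#' @param dot_distribution Named list mapping agent class to `mean_days`
#'   (days of therapy are `1 + Poisson(mean_days - 1)`).
#' @param class_mix Named proportions over agent classes for the primary
#'   course; must sum to 1.
#' @param second_course_probability Probability of an additional course of a
#'   different class.
#' @param other_infection_concurrent_uti_rate Probability an
#'   other-infection record truly needed urinary-pathogen treatment.
#' @param seed Optional integer seed; identical seeds give identical
#'   cohorts.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(
    n = 124,
    syndrome_probabilities = c(pyelonephritis = 50, cystitis = 15,
                               other_infection = 13, asb = 46) / 124,
    asb_procedural_indication_fraction = 8 / 46,
    poor_historian_fraction = 36 / 124,
    asb_altered_mental_status_fraction = 9 / 38,
    urinalysis_availability = 85 / 124,
    marker_probabilities = list(
      uti = c(leukocyturia = 0.953, bacteria_seen = 0.594, nitrites_positive = 0.219),
      asb = c(leukocyturia = 0.946, bacteria_seen = 0.684, nitrites_positive = 0.184)
    ),
    leukocyte_count_distribution = list(
      uti = c(meanlog = log(170), sdlog = 1.8),
      asb = c(meanlog = log(32), sdlog = 1.8)
    ),
    dot_distribution = list(
      third_generation_cephalosporin = c(mean_days = 4.5),
      amoxicillin_clavulanate = c(mean_days = 3.5),
      other = c(mean_days = 6)
    ),
    class_mix = c(third_generation_cephalosporin = 0.26,
                  amoxicillin_clavulanate = 0.065, other = 0.675),
    second_course_probability = 0.25,
    other_infection_concurrent_uti_rate = 1 / 13,
    seed = NULL) {
  cfg <- list(
    n = n,
    syndrome_probabilities = syndrome_probabilities,
    asb_procedural_indication_fraction = asb_procedural_indication_fraction,
    poor_historian_fraction = poor_historian_fraction,
    asb_altered_mental_status_fraction = asb_altered_mental_status_fraction,
    urinalysis_availability = urinalysis_availability,
    marker_probabilities = marker_probabilities,
    leukocyte_count_distribution = leukocyte_count_distribution,
    dot_distribution = dot_distribution,
    class_mix = class_mix,
    second_course_probability = second_course_probability,
    other_infection_concurrent_uti_rate = other_infection_concurrent_uti_rate,
    seed = seed
  )
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_config <- function(cfg) {
  if (is.na(cfg$n) || cfg$n < 0 || cfg$n != round(cfg$n)) {
    abort("n must be a non-negative integer")
  }
  sp <- cfg$syndrome_probabilities
  if (!setequal(names(sp), c("pyelonephritis", "cystitis", "other_infection", "asb"))) {
    abort("syndrome_probabilities must name pyelonephritis, cystitis, other_infection, asb")
  }
  if (any(sp < 0) || abs(sum(sp) - 1) > 1e-9) {
    abort("syndrome_probabilities must be non-negative and sum to 1 (tolerance 1e-9)")
  }
  props <- c(cfg$asb_procedural_indication_fraction, cfg$poor_historian_fraction,
             cfg$asb_altered_mental_status_fraction, cfg$urinalysis_availability,
             cfg$second_course_probability, cfg$other_infection_concurrent_uti_rate,
             unlist(cfg$marker_probabilities), cfg$class_mix)
  if (any(props < 0 | props > 1)) abort("All proportions must lie in [0, 1]")
  if (abs(sum(cfg$class_mix) - 1) > 1e-9) abort("class_mix must sum to 1")
  if (!setequal(names(cfg$class_mix), names(cfg$dot_distribution))) {
    abort("class_mix and dot_distribution must name the same agent classes")
  }
  invisible(cfg)
}

# piecewise-linear age quantile function through the published summary
# (min 18, Q1 46, median 64, Q3 74.25, max 97)
sample_ages <- function(n) {
  u <- runif(n)
  stats::approx(c(0, 0.25, 0.5, 0.75, 1), c(18, 46, 64, 74.25, 97), xout = u)$y
}

#' Generate a synthetic cohort
#'
#' Samples `config$n` patient records whose symptoms, special-population
#' flags, urinalysis, antibiotic courses and adjudication fields are
#' mutually consistent with the sampled syndrome: pyelonephritis records
#' carry flank pain and/or fever without an alternate explanation and truly
#' needed treatment; cystitis records carry dysuria without fever;
#' other-infection records carry fever explained by the documented source
#' (and occasionally a concurrent true UTI); ASB records carry either a
#' procedural treatment indication (truly needed) or no attributable
#' symptoms (not needed, i.e. inappropriately treated).
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed overriding `config$seed`.
#' @return A validated cohort tibble of `config$n` records. Identical seeds
#'   give identical cohorts.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 30, seed = 1))
#' syndrome_counts(cdst_adjudicate(cohort))
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  validate_config(config)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  if (n == 0) return(uti_record()[0, ])

  sp <- config$syndrome_probabilities
  syndrome <- sample(names(sp), n, replace = TRUE, prob = sp)
  is_pyelo <- syndrome == "pyelonephritis"
  is_cyst <- syndrome == "cystitis"
  is_other <- syndrome == "other_infection"
  is_asb <- syndrome == "asb"

  rec <- tibble::tibble(
    record_id = sprintf("S%05d", seq_len(n)),
    age_years = pmax(18, round(sample_ages(n))),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(75, 49) / 124)
  )

  asb_proc <- is_asb & runif(n) < config$asb_procedural_indication_fraction
  rec$pregnant <- FALSE
  rec$pre_endourological_procedure <- asb_proc
  rec$renal_transplant_within_60_days <- FALSE

  flank <- is_pyelo & runif(n) < 0.7
  fever_pyelo <- is_pyelo & (runif(n) < 0.7 | !flank)  # ensure >= 1 criterion
  rec$flank_pain <- flank
  rec$fever <- fever_pyelo | is_other
  rec$clinical_instability <- is_pyelo & runif(n) < 0.15
  rec$dysuria <- is_cyst | (is_pyelo & runif(n) < 0.3)
  rec$urgency <- is_cyst & runif(n) < 0.4
  rec$frequency <- is_cyst & runif(n) < 0.4
  rec$suprapubic_pain <- is_cyst & runif(n) < 0.2
  rec$pelvic_discomfort <- FALSE

  asb_ams <- is_asb & !asb_proc &
    runif(n) < config$asb_altered_mental_status_fraction
  rec$acute_mental_status_change <- asb_ams

  src <- rep("none", n)
  src[is_other] <- sample(non_urinary_sources, sum(is_other), replace = TRUE)
  rec$documented_non_urinary_source <- src
  alt <- rep(NA_character_, n)
  alt[is_other] <- src[is_other]
  ams_causes <- c("seizure", "psychotic_event", "severe_hyponatremia",
                  "hyperammonemia", "alcohol_intoxication", "shock")
  alt[asb_ams] <- sample(ams_causes, sum(asb_ams), replace = TRUE)
  rec$alternate_explanation_for_systemic <- alt

  rec$poor_historian <- runif(n) < config$poor_historian_fraction

  rec$truly_needed <- is_pyelo | is_cyst | asb_proc |
    (is_other & runif(n) < config$other_infection_concurrent_uti_rate)

  ua <- runif(n) < config$urinalysis_availability
  rec$ua_available <- ua
  mp <- config$marker_probabilities
  grp_uti <- is_pyelo | is_cyst
  for (m in urinalysis_markers) {
    p <- ifelse(grp_uti, mp$uti[[m]], mp$asb[[m]])
    rec[[m]] <- ifelse(ua, runif(n) < p, NA)
  }
  lcd <- config$leukocyte_count_distribution
  meanlog <- ifelse(grp_uti, lcd$uti[["meanlog"]], lcd$asb[["meanlog"]])
  sdlog <- ifelse(grp_uti, lcd$uti[["sdlog"]], lcd$asb[["sdlog"]])
  rec$leukocyte_count <- ifelse(ua, round(rlnorm(n, meanlog, sdlog), 1), NA_real_)

  rec$courses <- sample_courses(n, config)
  rec$notes <- NA_character_

  validate_cohort(rec[, cohort_columns()])
}

sample_courses <- function(n, config) {
  classes <- names(config$class_mix)
  mean_days <- vapply(config$dot_distribution, function(d) d[["mean_days"]],
                      numeric(1))
  primary <- sample(classes, n, replace = TRUE, prob = config$class_mix)
  second_on <- runif(n) < config$second_course_probability
  lapply(seq_len(n), function(i) {
    cls <- primary[i]
    if (second_on[i]) {
      pool <- setdiff(classes, cls)
      cls <- c(cls, sample(pool, 1))
    }
    tibble::tibble(
      agent_class = cls,
      days_of_therapy = 1L + rpois(length(cls), pmax(0, mean_days[cls] - 1))
    )
  })
}
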