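# Deterministic 124-record validation cohort.
#
# Stratum layout (record indices):
#   1-50    pyelonephritis    truly_needed, tool fires Q2 (flank pain) or Q3
#   51-65   cystitis          truly_needed, tool fires Q2 (record 51: pregnant, Q1)
#   66-78   other infection   fever explained by the documented source, tool
#                             silent; record 66 is the pneumonia case that
#                             developed E. coli bacteremia (truly_needed)
#   79-86   ASB, procedural   pre-endourological indication, tool fires Q1
#   87-124  ASB, no indication (inappropriately treated; 87-95 have altered
#                             mental status with a documented alternate cause)
#
# Tool-vs-truth margins: tp = 50+15+8 = 73, fn = 1 (record 66), tn = 38+12 = 50.
# The antibiotic-day schedule is a fixed allocation reproducing the published
# stratum totals (787 overall / 265 unjustified; cephalosporins 203/91;
# amoxicillin-clavulanate 51/21); per-patient durations are a design choice,
# only the stratum totals are load-bearing.

# split `total` days over n records as evenly as possible (deterministic)
distribute_days <- function(total, n) {
  base <- total %/% n
  extra <- total %% n
  rep(base, n) + rep(c(1L, 0L), c(extra, n - extra))
}

# sorted age vector pinned to median 64 and quartiles 46 / 74.25 (type-7)
fixture_ages_sorted <- function() {
  ages <- numeric(124)
  ages[1:30] <- round(seq(18, 45, length.out = 30))
  ages[31:32] <- 46
  ages[33:61] <- round(seq(47, 63, length.out = 29))
  ages[62:63] <- 64
  ages[64:92] <- round(seq(65, 73, length.out = 29))
  ages[93] <- 74
  ages[94] <- 75
  ages[95:124] <- round(seq(75, 97, length.out = 30))
  ages
}

fixture_strata <- function() {
  list(
    pyelonephritis = 1:50,
    cystitis = 51:65,
    other_infection = 66:78,
    asb_procedural = 79:86,
    asb_no_indication = 87:124
  )
}

#' Build the deterministic validation fixture cohort
#'
#' Constructs, without randomness, a 124-record cohort that satisfies every
#' published marginal count of the validation study simultaneously: syndrome
#' mix 50 pyelonephritis / 15 cystitis / 13 other infection / 46 ASB (8 of
#' them with a pre-procedural treatment indication); 36 poor historians; 38
#' records treated without any documented indication; 9 ASB records with
#' altered mental status attributable to another cause; tool-versus-truth
#' margins tp = 73, fp = 0, fn = 1 (a pneumonia case that developed E. coli
#' bacteremia and bacteriuria), tn = 50; 787 antibiotic days of which 265 on
#' inappropriately treated records, with 203/91 third-generation
#' cephalosporin and 51/21 amoxicillin-clavulanate (total/unjustified) days;
#' 75 female including 1 pregnant patient (classified cystitis); median age
#' 64 (IQR 46-74.25). An internal self-check recomputes all of these at
#' build time and errors if any fails.
#'
#' @return A validated cohort tibble of 124 records.
#' @examples
#' cohort <- build_fixture()
#' glance(cdst_validate(cohort))
#' @export
build_fixture <- function() {
  n <- 124
  s <- fixture_strata()
  idx <- seq_len(n)

  rec <- tibble::tibble(record_id = sprintf("R%03d", idx))

  # demographics: 75 female (ensuring the pregnant cystitis record is female)
  female_idx <- c(1:40, 51:65, 79:86, 87:98)
  rec$sex <- ifelse(idx %in% female_idx, "female", "male")
  # ages: pinned sorted vector dealt through a fixed permutation so strata
  # are not age-ordered (53 is coprime with 124)
  perm <- ((idx * 53L) %% 124L) + 1L
  ages <- numeric(n)
  ages[perm] <- fixture_ages_sorted()
  rec$age_years <- ages

  rec$pregnant <- idx == 51
  rec$pre_endourological_procedure <- idx %in% s$asb_procedural
  rec$renal_transplant_within_60_days <- FALSE

  # localized symptoms
  rec$urgency <- idx %in% 51:56
  rec$frequency <- idx %in% 52:55
  rec$dysuria <- idx %in% c(1:10, 51:65)
  rec$suprapubic_pain <- idx %in% 57:59
  rec$pelvic_discomfort <- FALSE
  rec$flank_pain <- idx %in% 1:35

  # systemic signs
  rec$fever <- idx %in% c(20:50, 66:78)
  rec$clinical_instability <- idx %in% 46:50
  rec$acute_mental_status_change <- idx %in% 87:95

  # alternate explanations: the 13 other-infection records' fever is
  # explained by the documented source; the 9 ASB altered-mental-status
  # episodes have documented non-urinary causes
  src <- rep("none", n)
  src[66:69] <- "pneumonia"
  src[70:73] <- "intra_abdominal"
  src[74:75] <- "osteomyelitis_decubitus"
  src[76] <- "covid19"
  src[77] <- "cellulitis"
  src[78] <- "epididymitis"
  rec$documented_non_urinary_source <- src
  alt <- rep(NA_character_, n)
  alt[66:78] <- src[66:78]
  alt[87:95] <- c("seizure", "psychotic_event", "severe_hyponatremia",
                  "hyperammonemia", "alcohol_intoxication", "hallucinations",
                  "cardiogenic_shock", "hypovolemic_shock", "seizure")
  rec$alternate_explanation_for_systemic <- alt

  # 36 poor historians: 10 pyelonephritis, 2 other infection, 9 ASB with
  # altered mental status, 15 further ASB records
  rec$poor_historian <- idx %in% c(41:50, 74:75, 87:95, 96:110)

  # reference standard
  rec$truly_needed <- idx %in% c(s$pyelonephritis, s$cystitis, 66, s$asb_procedural)

  # urinalysis: available for 58 UTI records and 27 ASB records (plus 6
  # other-infection records, unused by the published group comparison)
  ua_idx <- c(1:50, 51:58, 66:71, 79:86, 87:105)
  rec$ua_available <- idx %in% ua_idx
  rec$leukocyturia <- ifelse(rec$ua_available, !(idx %in% c(3, 7, 11, 90)), NA)
  rec$bacteria_seen <- ifelse(rec$ua_available, idx %% 5 <= 2, NA)
  rec$nitrites_positive <- ifelse(rec$ua_available, idx %% 5 == 0, NA)
  # right-skewed counts: a few very high values among the UTI records
  lc <- rep(NA_real_, n)
  lc[ua_idx] <- 40 + (match(ua_idx, ua_idx) * 37) %% 180
  lc[c(2, 9, 17, 25, 33, 41, 52)] <- c(4200, 6800, 2500, 9500, 3100, 5400, 7200)
  lc[c(88, 94)] <- c(1400, 900)
  rec$leukocyte_count <- lc

  rec$notes <- NA_character_
  rec$notes[66] <- paste("initial diagnosis of pneumonia; E. coli in blood and",
                         "urine on review, concurrent UTI")
  rec$notes[124] <- paste("pelvic pain after trauma with kidney laceration;",
                          "pain attributed to the laceration, not the urinary tract")

  rec$courses <- fixture_courses()

  cohort <- validate_cohort(rec[, cohort_columns()])
  fixture_self_check(cohort)
  cohort
}

# fixed antibiotic-day schedule; totals asserted by fixture_self_check()
fixture_courses <- function() {
  n <- 124
  ceph <- integer(n)
  amox <- integer(n)
  other <- integer(n)
  # appropriately treated records (1-86): 522 days
  ceph[1:28] <- 4L                                  # 112 cephalosporin days
  amox[51:60] <- 3L                                 # 30 amox-clav days
  other[1:86] <- distribute_days(380L, 86L)         # 380 other-class days
  # inappropriately treated records (87-124): 265 days
  ceph[87:116] <- distribute_days(91L, 30L)         # 91 cephalosporin days
  amox[117:124] <- distribute_days(21L, 8L)         # 21 amox-clav days
  other[87:124] <- distribute_days(153L, 38L)       # 153 other-class days
  lapply(seq_len(n), function(i) {
    cls <- c("third_generation_cephalosporin", "amoxicillin_clavulanate", "other")
    dot <- c(ceph[i], amox[i], other[i])
    keep <- dot > 0
    tibble::tibble(agent_class = cls[keep], days_of_therapy = as.integer(dot[keep]))
  })
}

fixture_self_check <- function(cohort) {
  check <- function(ok, what) {
    if (!isTRUE(ok)) abort(paste0("Fixture self-check failed: ", what))
  }
  labels <- cdst_adjudicate(cohort)
  counts <- table(labels$syndrome)
  check(nrow(cohort) == 124, "cohort size 124")
  check(counts[["pyelonephritis"]] == 50, "50 pyelonephritis")
  check(counts[["cystitis"]] == 15, "15 cystitis")
  check(counts[["other_infection"]] == 13, "13 other infections")
  check(counts[["asb"]] == 46, "46 ASB")
  check(sum(labels$asb_with_treatment_indication) == 8, "8 ASB with procedural indication")
  check(sum(labels$inappropriate) == 38, "38 treated without indication")
  check(sum(cohort$poor_historian) == 36, "36 poor historians")
  check(sum(cohort$acute_mental_status_change &
              !is.na(cohort$alternate_explanation_for_systemic) &
              labels$syndrome == "asb") == 9,
        "9 ASB with explained altered mental status")
  cm <- cdst_confusion(cdst_evaluate(cohort), cdst_true_need(cohort))
  check(cm$tp == 73 && cm$fp == 0 && cm$fn == 1 && cm$tn == 50,
        "confusion margins 73/0/1/50")
  bs <- cdst_burden(cohort, labels)
  check(bs$total_days == 787, "787 antibiotic days")
  check(bs$unjustified_days == 265, "265 unjustified days")
  ceph <- bs$by_class[bs$by_class$agent_class == "third_generation_cephalosporin", ]
  amox <- bs$by_class[bs$by_class$agent_class == "amoxicillin_clavulanate", ]
  check(ceph$total_days == 203 && ceph$unjustified_days == 91,
        "cephalosporin days 203/91")
  check(amox$total_days == 51 && amox$unjustified_days == 21,
        "amoxicillin-clavulanate days 51/21")
  check(sum(cohort$sex == "female") == 75, "75 female")
  check(sum(cohort$pregnant) == 1 &&
          labels$syndrome[cohort$pregnant] == "cystitis",
        "1 pregnant patient, classified cystitis")
  q <- unname(stats::quantile(cohort$age_years, c(0.25, 0.5, 0.75)))
  check(isTRUE(all.equal(q, c(46, 64, 74.25))), "age median 64, IQR 46-74.25")
  invisible(cohort)
}
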